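DATASET_SCHEMA <- "bedradar-dataset/1"

#' Persist / restore a generated dataset
#'
#' Datasets are written as a single versioned container holding every
#' sample's frame arrays plus the manifest; `load_dataset(save_dataset(x))`
#' reproduces all arrays bit-exactly with their labels and attributes. A
#' file written under a different schema version is refused with the
#' version named.
#'
#' @param dataset A list with `samples` and `manifest`, as returned by
#'   [generate_dataset()].
#' @param path File path (conventionally `.rds`).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   restored dataset list.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(is.list(dataset), !is.null(dataset$manifest))
  obj <- list(schema = DATASET_SCHEMA,
              manifest = dataset$manifest,
              samples = dataset$samples)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dataset
#' @param required_radars Optional radar ids every sample must carry;
#'   a missing radar raises a data error naming it.
#' @export
load_dataset <- function(path, required_radars = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$schema, DATASET_SCHEMA)) {
    stop("dataset schema mismatch: file has '", obj$schema %||% "<none>",
         "', this package reads '", DATASET_SCHEMA, "'", call. = FALSE)
  }
  if (!is.null(obj$samples) && !is.null(required_radars)) {
    for (s in obj$samples) {
      missing_ids <- setdiff(required_radars, names(s$frames))
      if (length(missing_ids)) {
        stop("sample ", s$sample_id, " is missing radar group(s): ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
      }
    }
  }
  list(samples = obj$samples, manifest = obj$manifest)
}

#' Export an echo map as an 8-bit grayscale PNG
#'
#' The map is min-max scaled to [0, 255]; a constant map exports as all
#' zeros (never NaN). The image is written with the bed length down the
#' image rows (y increasing from headboard to foot), so its dimensions are
#' `n_y` x `n_x`.
#'
#' @param srem An `srem`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_srem_png <- function(srem, path) {
  stopifnot(inherits(srem, "srem"))
  v <- srem$values
  if (!all(is.finite(v))) stop("map must be finite", call. = FALSE)
  rng <- range(v)
  img <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png::writePNG(t(img), path)  # rows = y (bed length), cols = x
  invisible(path)
}

#' Write a machine-readable run record
#'
#' Every pipeline stage writes a JSON record next to its outputs: the
#' stage name, the configuration (hashed for compactness plus echoed in
#' full), the seed, the package version and a timestamp.
#'
#' @param stage Stage name (e.g. `"simulate"`).
#' @param config List of the parameters the stage ran with.
#' @param seed The seed used.
#' @param path Output path for the JSON record.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(stage, config, seed, path) {
  rec <- list(
    stage = stage,
    package = "bedradar",
    version = as.character(utils::packageVersion("bedradar")),
    seed = seed,
    config = config,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# order-stable FNV-1a style hash of the serialised config
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 2166136261
  for (cp in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), cp) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
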