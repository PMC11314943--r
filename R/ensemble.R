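#' Ensemble configuration
#'
#' A boolean mask over the eight canonical radar slots, identifying which
#' radars a model configuration retains.
#'
#' @param mask Logical vector named by (a subset of) `radar_slots()`;
#'   unnamed slots are taken as `FALSE`.
#' @param config_id Registry number (1-22) or a custom identifier.
#' @param note Free-text description.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(mask, config_id = NA, note = "") {
  full <- stats::setNames(rep(FALSE, 8L), radar_slots())
  if (is.character(mask)) {
    bad <- setdiff(mask, radar_slots())
    if (length(bad)) stop("unknown radar slot(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[mask] <- TRUE
  } else {
    stopifnot(is.logical(mask), !is.null(names(mask)))
    bad <- setdiff(names(mask), radar_slots())
    if (length(bad)) stop("unknown radar slot(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(mask)] <- mask
  }
  n <- sum(full)
  if (n < 1L) stop("an ensemble must retain at least one radar",
                   call. = FALSE)
  structure(
    list(config_id = config_id, mask = full, n_radars = n, note = note),
    class = "ensemble_config"
  )
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf("<ensemble_config #%s> %d radars: %s%s\n",
              as.character(x$config_id), x$n_radars,
              paste(names(x$mask)[x$mask], collapse = ", "),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

table3_path <- function() {
  system.file("extdata", "table3_configurations.csv", package = "bedradar",
              mustWork = TRUE)
}

#' The 22-configuration ablation registry
#'
#' The pre-planned radar subset configurations of the bench ablation
#' protocol, in order: the 8-radar baseline; single head-radar removals;
#' single retained head radars; side-radar removals with the central head
#' radar kept; the no-head-radar set; four-radar subsets; and the minimal
#' two-radar pair (central side + central head). Radar counts per row are
#' 8,7,7,7,6,6,6,5,5,5,5,5,5,4,4,4,4,4,4,4,3,2.
#'
#' @return List of 22 `ensemble_config`, names `"1"`..`"22"`.
#' @examples
#' reg <- config_registry()
#' reg[["22"]]
#' @export
config_registry <- function() {
  df <- utils::read.csv(table3_path(), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(k) {
    mask <- stats::setNames(as.logical(unlist(df[k, radar_slots()])),
                            radar_slots())
    ensemble_config(mask, config_id = df$config_id[k], note = df$note[k])
  })
  names(out) <- as.character(df$config_id)
  out
}

#' Published per-configuration accuracies
#'
#' The packaged table of four-class classification accuracies reported for
#' every registry configuration under four deep feature extractors, in
#' tidy long form. Used to exercise the radar-count aggregation without
#' retraining.
#'
#' @return Tibble: config_id, n_radars, model, accuracy, note.
#' @export
reference_accuracies <- function() {
  df <- utils::read.csv(table3_path(), stringsAsFactors = FALSE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(df),
    cols = c("densenet121", "resnet50", "efficientnet_b0", "phresnet50"),
    names_to = "model", values_to = "accuracy"
  )
  long[, c("config_id", "n_radars", "model", "accuracy", "note")]
}

#' Subject-wise train/test split
#'
#' Splits subjects (not samples) into disjoint training and testing sets,
#' so no subject contributes to both sides. Defaults preserve the 55:15
#' subject proportion of the bench protocol for any subject count
#' (train_n = round(n * 55/70)).
#'
#' @param subject_ids Character vector of distinct subject identifiers.
#' @param train_n,test_n Subject counts; both default to the 55:15
#'   proportion of `length(subject_ids)`.
#' @param seed RNG seed for the random assignment.
#' @return List with `train` and `test` character vectors.
#' @examples
#' subject_split(sprintf("sub%02d", 1:14), seed = 1)
#' @export
subject_split <- function(subject_ids, train_n = NULL, test_n = NULL,
                          seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (is.null(train_n)) train_n <- round(n * 55 / 70)
  if (is.null(test_n)) test_n <- n - train_n
  if (train_n + test_n > n) {
    stop("train_n + test_n exceeds the number of subjects", call. = FALSE)
  }
  withr_seed(seed, {
    shuffled <- sample(subject_ids)
  })
  list(train = sort(shuffled[seq_len(train_n)]),
       test = sort(shuffled[train_n + seq_len(test_n)]))
}

#' Run the radar-ablation protocol
#'
#' For each ensemble configuration: build the view stacks under the mask,
#' train a fresh model on the training subjects, evaluate on the held-out
#' subjects, and record the accuracy. One shared subject split is used
#' across all configurations so accuracy differences reflect the radar
#' masks only. Per-configuration training seeds are offset by the
#' config_id for reproducibility.
#'
#' @param samples List of `sample_record` (must cover all radars any
#'   config requests).
#' @param manifest Manifest tibble matching `samples` (same order).
#' @param configs List of `ensemble_config` (e.g. from
#'   [config_registry()]), or `NULL` for the full registry.
#' @param spec A `model_spec` (its `n_views` is overridden per config).
#' @param config A `train_config`.
#' @param placement,grid Geometry.
#' @param classes `"coarse"` (4-class, the protocol default) or `"fine"`.
#' @param seed Split / base training seed.
#' @param input_size Model input side length.
#' @return Tibble of class results: config_id, n_radars, mask, model,
#'   seed, accuracy.
#' @export
run_ablation <- function(samples, manifest, configs = NULL,
                         spec = model_spec(), config = train_config(),
                         placement = default_placement(),
                         grid = grid_spec(),
                         classes = c("coarse", "fine"),
                         seed = 1L, input_size = spec$input_size) {
  classes <- match.arg(classes)
  if (is.null(configs)) configs <- config_registry()
  if (inherits(configs, "ensemble_config")) configs <- list(configs)
  have <- names(samples[[1]]$frames)
  for (cf in configs) {
    missing_ids <- setdiff(names(cf$mask)[cf$mask], have)
    if (length(missing_ids)) {
      stop("config ", cf$config_id, " requests radar(s) missing from the ",
           "dataset: ", paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  labels <- if (classes == "coarse") {
    coarse_map(manifest$posture)
  } else {
    factor(manifest$posture, levels = posture_levels())
  }
  split <- subject_split(manifest$subject_id, seed = seed)
  tr <- manifest$subject_id %in% split$train
  te <- manifest$subject_id %in% split$test

  # the full 8-view stack is built once; each config subsets its views
  full <- stack_views_array(samples, placement, grid, mask = NULL,
                            input_size = input_size)
  rows <- lapply(configs, function(cf) {
    vsel <- match(names(cf$mask)[cf$mask], full$radar_ids)
    x <- full$x[, vsel, , , drop = FALSE]
    sp <- spec
    sp$n_views <- length(vsel)
    cfg_seed <- as.integer((seed + 1000L * as_config_offset(cf$config_id)) %%
                             2147483647)
    tc <- config
    tc$seed <- cfg_seed
    model <- build_model(sp, seed = cfg_seed)
    model <- train_mvcnn(model, x[tr, , , , drop = FALSE], labels[tr], tc)
    ev <- evaluate_model(model, x[te, , , , drop = FALSE], labels[te])
    tibble::tibble(
      config_id = cf$config_id,
      n_radars = cf$n_radars,
      mask = paste(names(cf$mask)[cf$mask], collapse = "+"),
      model = sp$backbone,
      seed = cfg_seed,
      accuracy = ev$accuracy
    )
  })
  dplyr::bind_rows(rows)
}

as_config_offset <- function(config_id) {
  v <- suppressWarnings(as.integer(config_id))
  if (is.na(v)) sum(utf8ToInt(as.character(config_id))) %% 1000L else v
}

#' Aggregate ablation accuracies by radar count
#'
#' Arithmetic mean accuracy per (model, number of radars), half-up rounded
#' to 3 decimals, groups ordered by descending radar count — the summary
#' arithmetic of the bench protocol's radar-count table. Works on live
#' ablation results or on [reference_accuracies()].
#'
#' @param results Data frame with columns `model`, `n_radars`, `accuracy`.
#' @param digits Rounding digits (half-up).
#' @return Tibble: model, n_radars, mean_accuracy, n_configs.
#' @examples
#' aggregate_by_count(reference_accuracies())
#' @export
aggregate_by_count <- function(results, digits = 3L) {
  stopifnot(all(c("model", "n_radars", "accuracy") %in% names(results)))
  out <- results |>
    dplyr::group_by(.data$model, .data$n_radars) |>
    dplyr::summarise(
      mean_accuracy = round_half_up(mean(.data$accuracy), digits),
      n_configs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$model, dplyr::desc(.data$n_radars))
  out
}

# Half-up decimal rounding (R's round() is half-to-even); the tiny epsilon
# absorbs binary representation error in decimal inputs.
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
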