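#' Generate a Spatial Radar Echo Map
#'
#' Back-projects a radar's 1D range-intensity profile onto the shared 2D
#' bed grid: every grid cell receives an interpolation of the two range bins
#' bracketing its distance to the radar. With `d` the bin spacing in cm and
#' `D` the cell-radar distance, the bracketing (0-based) bins are
#' `b_small = floor(D/d)` and `b_large = ceil(D/d)`.
#'
#' Two interpolation weightings are provided. `"as_printed"` follows the
#' published algorithm verbatim, weighting `b_small` by `(D mod d)/d` and
#' `b_large` by `1 - (D mod d)/d` — note this gives the fractional distance
#' to the *nearer* bin, the inverse of standard linear interpolation.
#' `"corrected"` uses the standard weighting (`b_small` gets
#' `1 - (D mod d)/d`). The two coincide wherever `D` is an exact bin
#' multiple, and both pairs of weights sum to 1 at every cell.
#'
#' Cells whose far bracket falls beyond the profile (`b_large >= n_bins`)
#' get zero. With `masked = TRUE` (default) cells outside the radar's
#' azimuth sector are also zeroed, yielding the characteristic sector-shaped
#' support; the unmasked map is the algorithm's literal output.
#'
#' @param profile An `intensity_profile` of length `radar$n_bins`.
#' @param radar A `radar_spec`.
#' @param grid A `grid_spec` (units cm; bin spacing is converted with
#'   `d = max_range * 100 / n_bins`).
#' @param interp `"as_printed"` or `"corrected"`.
#' @param masked Zero cells outside the azimuth sector?
#' @param dist_mode Distance mode passed to [distance_map()].
#' @param D Optional precomputed distance matrix (saves recomputation when
#'   mapping many profiles through one radar/grid pairing).
#' @param sector Optional precomputed azimuth mask.
#' @return An object of class `srem`: `values` (`n_x` x `n_y` matrix),
#'   `grid`, `radar_id`, `interp`, `masked`.
#' @examples
#' g <- grid_spec(extent = c(10, 10), cell_size = 1)
#' r <- radar_spec("HC", c(5, -2), c(0, 1), n_bins = 64,
#'                 max_range = 0.64, bin_length = 0.01)
#' p <- intensity_profile(rep(1, 64), bin_length = 0.01)
#' m <- generate_srem(p, r, g)
#' @export
generate_srem <- function(profile, radar, grid,
                          interp = c("as_printed", "corrected"),
                          masked = TRUE,
                          dist_mode = "planar",
                          D = NULL, sector = NULL) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(radar, "radar_spec"), inherits(grid, "grid_spec"))
  interp <- match.arg(interp)
  if (length(profile$values) != radar$n_bins) {
    stop("profile length (", length(profile$values),
         ") must equal radar n_bins (", radar$n_bins, ")", call. = FALSE)
  }
  if (abs(profile$bin_length - radar$bin_length) > 1e-9) {
    stop("profile and radar bin lengths disagree: unit mismatch",
         call. = FALSE)
  }
  d <- radar$max_range * 100 / radar$n_bins  # bin spacing, cm
  if (is.null(D)) D <- distance_map(radar, grid, mode = dist_mode)
  b_small <- floor(D / d)        # 0-based bin indices
  b_large <- ceiling(D / d)
  frac <- (D %% d) / d
  R <- profile$values
  in_range <- b_large < radar$n_bins  # b_large is 0-based: needs < n_bins
  Q <- matrix(0, grid$n_x, grid$n_y)
  if (any(in_range)) {
    lo <- R[b_small[in_range] + 1L]
    hi <- R[b_large[in_range] + 1L]
    Q[in_range] <- if (interp == "as_printed") {
      lo * frac[in_range] + hi * (1 - frac[in_range])
    } else {
      lo * (1 - frac[in_range]) + hi * frac[in_range]
    }
  }
  if (masked) {
    if (is.null(sector)) sector <- azimuth_mask(radar, grid)
    Q[!sector] <- 0
  }
  structure(
    list(values = Q, grid = grid, radar_id = radar$radar_id,
         interp = interp, masked = masked),
    class = "srem"
  )
}

#' @export
print.srem <- function(x, ...) {
  cat(sprintf("<srem %s> %d x %d cells, interp=%s, masked=%s, peak %.4g\n",
              x$radar_id, nrow(x$values), ncol(x$values), x$interp,
              x$masked, max(x$values)))
  invisible(x)
}

#' Accumulate echo maps over several frames
#'
#' Sums the per-profile maps of several profiles from the same radar (the
#' multi-frame accumulation loop of the map-generation algorithm). By
#' linearity the result equals the element-wise sum of the individual maps.
#'
#' @param profiles List of `intensity_profile`, all the same length.
#' @inheritParams generate_srem
#' @return An `srem` whose `radar_id` is the radar's.
#' @export
accumulate_srem <- function(profiles, radar, grid,
                            interp = c("as_printed", "corrected"),
                            masked = TRUE, dist_mode = "planar") {
  if (length(profiles) == 0L) {
    stop("`profiles` must contain at least one profile", call. = FALSE)
  }
  interp <- match.arg(interp)
  D <- distance_map(radar, grid, mode = dist_mode)
  sector <- if (masked) azimuth_mask(radar, grid) else NULL
  maps <- lapply(profiles, generate_srem, radar = radar, grid = grid,
                 interp = interp, masked = masked, dist_mode = dist_mode,
                 D = D, sector = sector)
  out <- maps[[1]]
  if (length(maps) > 1) {
    out$values <- Reduce(`+`, lapply(maps, `[[`, "values"))
  }
  out
}

#' Build a multiview echo-map stack for one sample
#'
#' Runs the per-radar pipeline — clutter suppression, profile extraction,
#' echo-map generation — for every radar an ensemble mask retains, and
#' stacks the maps in canonical slot order (HL, HC, HR, S1..S5 filtered by
#' the mask). `per_view_minmax` rescales each view to [0, 1] independently
#' (a constant view maps to all zeros rather than NaN).
#'
#' @param sample A `sample_record`.
#' @param placement Named list of `radar_spec` covering the mask.
#' @param grid A `grid_spec`.
#' @param mask Logical vector named by radar slots (or an
#'   `ensemble_config`); `NULL` keeps every radar in `placement`.
#' @param normalization `"per_view_minmax"` or `"none"`.
#' @param interp,masked,dist_mode Passed to [generate_srem()].
#' @param profile_method Passed to [extract_profile()].
#' @param geom_cache Optional cache from [precompute_geometry()].
#' @return An object of class `view_stack`: `views` (named list of `srem`),
#'   `radar_ids`, `grid`, `normalization`.
#' @export
build_view_stack <- function(sample, placement, grid, mask = NULL,
                             normalization = c("per_view_minmax", "none"),
                             interp = "as_printed", masked = TRUE,
                             dist_mode = "planar",
                             profile_method = "envelope",
                             geom_cache = NULL) {
  stopifnot(inherits(sample, "sample_record"))
  normalization <- match.arg(normalization)
  active <- active_radars(mask, placement)
  missing_ids <- setdiff(active, names(sample$frames))
  if (length(missing_ids)) {
    stop("sample ", sample$sample_id, " lacks frames for radar(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  views <- lapply(active, function(id) {
    radar <- placement[[id]]
    cache <- geom_cache[[id]]
    prof <- extract_profile(clutter_suppress(sample$frames[[id]]),
                            method = profile_method)
    m <- generate_srem(prof, radar, grid, interp = interp, masked = masked,
                       dist_mode = dist_mode,
                       D = cache$D, sector = cache$sector)
    if (normalization == "per_view_minmax") {
      rng <- range(m$values)
      m$values <- if (diff(rng) > 0) (m$values - rng[1]) / diff(rng)
                  else m$values * 0
    }
    m
  })
  names(views) <- active
  structure(
    list(views = views, radar_ids = active, grid = grid,
         normalization = normalization),
    class = "view_stack"
  )
}

# Resolve an ensemble mask to the active radar ids in canonical order.
active_radars <- function(mask, placement) {
  if (is.null(mask)) {
    ids <- intersect(radar_slots(), names(placement))
    return(c(ids, setdiff(names(placement), radar_slots())))
  }
  if (inherits(mask, "ensemble_config")) mask <- mask$mask
  stopifnot(is.logical(mask), !is.null(names(mask)))
  ids <- names(mask)[mask]
  ids <- intersect(radar_slots(), ids)
  absent <- setdiff(ids, names(placement))
  if (length(absent)) {
    stop("mask requests radar(s) absent from placement: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Precompute per-radar distance maps and sector masks
#'
#' Distance and azimuth geometry depend only on the radar/grid pairing, so
#' when mapping many samples they are computed once and passed to
#' [build_view_stack()] via `geom_cache`.
#'
#' @param placement Named list of `radar_spec`.
#' @param grid A `grid_spec`.
#' @param dist_mode Distance mode.
#' @return Named list per radar with elements `D` and `sector`.
#' @export
precompute_geometry <- function(placement, grid, dist_mode = "planar") {
  lapply(placement, function(r) {
    list(D = distance_map(r, grid, mode = dist_mode),
         sector = azimuth_mask(r, grid))
  })
}

#' @export
print.view_stack <- function(x, ...) {
  cat(sprintf("<view_stack> %d views (%s), %d x %d cells, normalization=%s\n",
              length(x$views), paste(x$radar_ids, collapse = ", "),
              x$grid$n_x, x$grid$n_y, x$normalization))
  invisible(x)
}

#' Bilinear resize of a numeric matrix
#'
#' Downsamples an echo map to the square input size the network backbone
#' expects, by bilinear interpolation on cell-centre coordinates.
#'
#' @param mat Numeric matrix.
#' @param size Output side length (pixels); output is `size` x `size`.
#' @return A `size` x `size` matrix.
#' @export
resize_bilinear <- function(mat, size) {
  nr <- nrow(mat); nc <- ncol(mat)
  # source coordinates of target pixel centres
  sr <- (seq_len(size) - 0.5) * nr / size + 0.5
  sc <- (seq_len(size) - 0.5) * nc / size + 0.5
  r0 <- pmin(pmax(floor(sr), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(sc), 1), nc); c1 <- pmin(c0 + 1, nc)
  wr <- pmin(pmax(sr - r0, 0), 1); wc <- pmin(pmax(sc - c0, 0), 1)
  a <- mat[r0, c0, drop = FALSE]; b <- mat[r1, c0, drop = FALSE]
  d <- mat[r0, c1, drop = FALSE]; e <- mat[r1, c1, drop = FALSE]
  top <- a * (1 - wr) + b * wr        # wr recycles down columns
  bot <- d * (1 - wr) + e * wr
  sweep(top, 2, 1 - wc, `*`) + sweep(bot, 2, wc, `*`)
}

#' Plot an echo map
#'
#' Renders the map as a raster in bed coordinates, y increasing from the
#' headboard towards the foot of the bed.
#'
#' @param object An `srem`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srem <- function(object, ...) {
  ax <- grid_axes(object$grid)
  df <- tidyr::expand_grid(y = ax$y, x = ax$x)
  df$intensity <- as.vector(object$values)  # column-major: x fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("SREM", object$radar_id),
                  x = "x (cm)", y = "y (cm, headboard at top)")
}
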