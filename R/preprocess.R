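#' Static clutter suppression by slow-time mean subtraction
#'
#' Removes returns that are constant over slow time (walls, bed frame,
#' antenna coupling) by subtracting, from every range bin, that bin's mean
#' over the slow-time pulses. After suppression each bin's slow-time series
#' has exactly zero mean, so the operation is idempotent and removes any
#' component that is static across pulses while leaving the varying part
#' untouched.
#'
#' @param frame A `radar_frame` with at least 2 slow-time pulses.
#' @return A `radar_frame` of the same shape.
#' @examples
#' f <- radar_frame(matrix(c(1, 2, 3, 2), 2, 2))
#' clutter_suppress(f)$values
#' @export
clutter_suppress <- function(frame) {
  stopifnot(inherits(frame, "radar_frame"))
  if (ncol(frame$values) < 2L) {
    stop("clutter suppression needs >= 2 slow-time pulses; ",
         "mean subtraction would null a single-pulse frame", call. = FALSE)
  }
  out <- frame
  out$values <- frame$values - rowMeans(frame$values)
  out
}

#' Extract a per-radar range-intensity profile
#'
#' Collapses a (clutter-suppressed) frame to the 1D non-negative intensity
#' vector that feeds echo-map generation. `"envelope"` (default) takes the
#' per-bin root-mean-square over slow time, robust to which pulse is
#' sampled; `"column"` takes the magnitude of a single slow-time pulse
#' (default the last), matching a single-instant readout.
#'
#' @param frame A `radar_frame`.
#' @param method `"envelope"` or `"column"`.
#' @param t Slow-time index for `method = "column"`; default `ncol`.
#' @return An `intensity_profile`: list with `values` (length `n_bins`,
#'   non-negative), `radar_id`, `bin_length`.
#' @export
extract_profile <- function(frame, method = c("envelope", "column"),
                            t = NULL) {
  stopifnot(inherits(frame, "radar_frame"))
  method <- match.arg(method)
  v <- frame$values
  if (method == "envelope") {
    prof <- sqrt(rowMeans(v^2))
  } else {
    t <- t %||% ncol(v)
    if (t < 1L || t > ncol(v)) {
      stop("slow-time index out of range: ", t, call. = FALSE)
    }
    prof <- abs(v[, t])
  }
  intensity_profile(prof, radar_id = frame$radar_id,
                    bin_length = frame$bin_length)
}

#' Intensity profile container
#'
#' @param values Non-negative numeric vector, one entry per range bin.
#' @param radar_id Radar identifier.
#' @param bin_length Range-bin length, metres.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(values, radar_id = "R", bin_length = 0.00643) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("profile must be finite", call. = FALSE)
  if (any(values < 0)) stop("profile must be non-negative", call. = FALSE)
  structure(list(values = values, radar_id = radar_id,
                 bin_length = bin_length),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile %s> %d bins, peak %.4g at bin %d\n",
              x$radar_id, length(x$values), max(x$values),
              which.max(x$values)))
  invisible(x)
}
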