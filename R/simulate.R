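#' Simulation parameters
#'
#' Controls the point-scatterer frame synthesis. The received pulse is
#' modelled as a sum of delayed returns, one per scatterer, plus additive
#' channel noise: each scatterer deposits an amplitude at the range bin
#' matching its distance, spread by a Gaussian range point-spread whose
#' width corresponds to the hardware's 1.4 GHz bandwidth
#' (sigma = c / (2 * bandwidth) ~ 0.107 m ~ 16.6 bins at 0.00643 m/bin).
#'
#' @param noise_sigma Standard deviation of the i.i.d. Gaussian channel
#'   noise, amplitude units.
#' @param clutter_amp Amplitude scale of the static clutter profile; the
#'   profile itself is a smooth random curve drawn per radar (constant
#'   across slow time) unless `clutter_profile` supplies one explicitly.
#' @param clutter_profile Optional explicit per-bin static clutter vector
#'   (recycled/truncated to `n_bins` at frame time).
#' @param blanket_attenuation Named multiplicative factors per blanket
#'   condition, each in (0, 1].
#' @param blanket_diffuse Reflectivity scale of the diffuse blanket
#'   scatterer layer added over the body (0 disables it).
#' @param psf_sigma_bins Gaussian range point-spread, in bins.
#' @param amplitude_exponent Path-loss exponent applied to range in metres.
#' @param scintillation_sd Relative pulse-to-pulse fluctuation of each
#'   scatterer's return (channel fading / residual micro-motion of a
#'   stationary body). This is what survives slow-time mean subtraction:
#'   with it at 0, body returns are perfectly static and are removed
#'   together with the clutter. No quasi-periodic (vital-sign) structure
#'   is modelled.
#' @param n_pulses Number of slow-time pulses per frame.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(noise_sigma = 0.01,
                       clutter_amp = 0.3,
                       clutter_profile = NULL,
                       blanket_attenuation = c(thick = 0.5, medium = 0.7,
                                               thin = 0.85),
                       blanket_diffuse = 0.08,
                       psf_sigma_bins = 16.6,
                       amplitude_exponent = 2,
                       scintillation_sd = 0.15,
                       n_pulses = 20L) {
  stopifnot(noise_sigma >= 0, psf_sigma_bins > 0, n_pulses >= 2,
            scintillation_sd >= 0,
            all(blanket_attenuation > 0), all(blanket_attenuation <= 1))
  structure(
    list(noise_sigma = noise_sigma,
         clutter_amp = clutter_amp,
         clutter_profile = clutter_profile,
         blanket_attenuation = blanket_attenuation,
         blanket_diffuse = blanket_diffuse,
         psf_sigma_bins = psf_sigma_bins,
         amplitude_exponent = amplitude_exponent,
         scintillation_sd = scintillation_sd,
         n_pulses = as.integer(n_pulses)),
    class = "sim_params"
  )
}

# Deterministic child seed from a root seed and a tuple of strings/ints,
# so every (subject, posture, blanket, trial, radar) cell has its own
# reproducible stream independent of generation order. Kept below 2^31.
child_seed <- function(root, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.numeric(root) %% 2147483647
  for (p in parts) {
    for (cp in utf8ToInt(p)) {
      h <- (h * 31 + cp) %% 2147483647
    }
  }
  as.integer(h)
}

# Smooth static clutter profile: low-pass filtered Gaussian noise.
default_clutter <- function(n_bins, amp) {
  raw <- stats::rnorm(n_bins)
  k <- stats::dnorm(seq(-40, 40), sd = 15)
  sm <- stats::filter(c(rev(raw[1:40]), raw, rev(raw[(n_bins - 39):n_bins])),
                      k / sum(k), sides = 2)
  amp * abs(as.numeric(sm[41:(40 + n_bins)]))
}

#' Simulate one radar frame
#'
#' Synthesises the 2D fast-time x slow-time intensity matrix a radar would
#' record from a posture phantom: per-scatterer returns at the matching
#' range bin (amplitude = reflectivity x blanket attenuation x cosine
#' azimuth taper / range^exponent, zero outside the azimuth sector, Gaussian
#' range spread), replicated across slow time, plus a static clutter profile
#' and i.i.d. Gaussian noise. Scatterers beyond the radar's maximum range
#' contribute nothing.
#'
#' @param radar A `radar_spec`.
#' @param phantom A `phantom`.
#' @param params A `sim_params`.
#' @param blanket One of `names(params$blanket_attenuation)`, or `NULL` for
#'   no blanket (attenuation 1, no diffuse layer).
#' @return A `radar_frame`: list with `values` (`n_bins` x `n_pulses`
#'   matrix), `radar_id`, `bin_length`.
#' @export
simulate_frame <- function(radar, phantom, params = sim_params(),
                           blanket = NULL) {
  stopifnot(inherits(radar, "radar_spec"), inherits(phantom, "phantom"),
            inherits(params, "sim_params"))
  att <- 1
  sc <- phantom$scatterers
  if (!is.null(blanket)) {
    if (!blanket %in% names(params$blanket_attenuation)) {
      stop("unknown blanket condition: ", blanket, call. = FALSE)
    }
    att <- params$blanket_attenuation[[blanket]]
    if (params$blanket_diffuse > 0 && nrow(sc) > 0) {
      # diffuse returns from the blanket surface draped over the body
      n_d <- 6L
      idx <- sample.int(nrow(sc), n_d, replace = TRUE)
      diffuse <- cbind(
        x = sc[idx, "x"] + stats::rnorm(n_d, 0, 6),
        y = sc[idx, "y"] + stats::rnorm(n_d, 0, 6),
        reflectivity = params$blanket_diffuse * (1 - att) *
          stats::runif(n_d, 0.5, 1.5)
      )
      sc <- rbind(sc, diffuse)
    }
  }
  n_bins <- radar$n_bins
  n_pulses <- params$n_pulses
  signal <- matrix(0, n_bins, n_pulses)
  bin_cm <- radar$bin_length * 100
  if (nrow(sc) > 0) {
    dx <- sc[, "x"] - radar$position[1]
    dy <- sc[, "y"] - radar$position[2]
    rng_cm <- sqrt(dx^2 + dy^2)
    ang <- acos(pmin(pmax(
      (dx * radar$boresight[1] + dy * radar$boresight[2]) /
        pmax(rng_cm, .Machine$double.eps), -1), 1)) * 180 / pi
    taper <- ifelse(ang <= radar$azimuth_half_angle,
                    cos(ang / radar$azimuth_half_angle * pi / 2), 0)
    rng_m <- pmax(rng_cm / 100, 0.1)  # clamp to avoid near-field blowup
    amp <- sc[, "reflectivity"] * att * taper / rng_m^params$amplitude_exponent
    bins <- seq_len(n_bins)
    for (i in seq_along(amp)) {
      # per-pulse multiplicative scintillation of this scatterer's return;
      # drawn even for skipped scatterers to keep the stream aligned
      gain <- 1 + if (params$scintillation_sd > 0) {
        stats::rnorm(n_pulses, 0, params$scintillation_sd)
      } else rep(0, n_pulses)
      if (amp[i] <= 0) next
      b0 <- rng_cm[i] / bin_cm  # 0-based fractional bin
      if (b0 >= n_bins) next    # beyond max range: no contribution
      psf <- exp(-((bins - 1) - b0)^2 / (2 * params$psf_sigma_bins^2))
      signal <- signal + (amp[i] * psf) %o% gain
    }
  }
  clut <- params$clutter_profile
  if (is.null(clut)) {
    clut <- default_clutter(n_bins, params$clutter_amp)
  } else {
    clut <- rep_len(as.numeric(clut), n_bins)
  }
  values <- signal + matrix(clut, nrow = n_bins, ncol = n_pulses)
  if (params$noise_sigma > 0) {
    values <- values +
      matrix(stats::rnorm(n_bins * n_pulses, 0, params$noise_sigma),
             n_bins, n_pulses)
  }
  radar_frame(values, radar_id = radar$radar_id,
              bin_length = radar$bin_length)
}

#' Radar frame container
#'
#' @param values `n_bins` x `n_pulses` numeric matrix: fast-time range bins
#'   down the rows, slow-time pulses across the columns.
#' @param radar_id Radar identifier.
#' @param bin_length Range-bin length, metres.
#' @return An object of class `radar_frame`.
#' @export
radar_frame <- function(values, radar_id = "R", bin_length = 0.00643) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("frame values must be finite",
                                    call. = FALSE)
  structure(list(values = values, radar_id = radar_id,
                 bin_length = bin_length),
            class = "radar_frame")
}

#' @export
print.radar_frame <- function(x, ...) {
  cat(sprintf("<radar_frame %s> %d bins x %d pulses\n",
              x$radar_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Generate a posture-labelled multi-radar dataset
#'
#' Produces one sample per (subject, posture, blanket, trial) tuple, each
#' holding one simulated frame per radar in the placement, plus a tidy
#' manifest. The full bench design is 70 subjects x 9 postures x 3 blanket
#' conditions x 3 trials = 5670 samples. Per-subject body scale is drawn
#' once per subject; every cell of the design has its own child RNG stream
#' derived from `seed`, so any subset regenerates identically regardless of
#' order.
#'
#' @param n_subjects Number of subjects.
#' @param postures Character vector of fine posture labels.
#' @param blankets Character vector of blanket conditions (subset of
#'   `names(params$blanket_attenuation)`).
#' @param trials Number of repeated trials.
#' @param placement Named list of `radar_spec` (default the 8-radar bench).
#' @param params A `sim_params`.
#' @param seed Integer root seed.
#' @param materialize Set `FALSE` to skip frame synthesis and return the
#'   manifest only (fast design-count checks).
#' @return List with `samples` (list of `sample_record`, `NULL` when not
#'   materialised) and `manifest` (tibble: sample_id, subject_id, posture,
#'   coarse_label, blanket, trial).
#' @examples
#' ds <- generate_dataset(2, postures = c("S", "L.Log"), blankets = "thin",
#'                        trials = 1, seed = 1)
#' ds$manifest
#' @export
generate_dataset <- function(n_subjects,
                             postures = posture_levels(),
                             blankets = c("thick", "medium", "thin"),
                             trials = 3,
                             placement = default_placement(),
                             params = sim_params(),
                             seed = 1L,
                             materialize = TRUE) {
  stopifnot(n_subjects >= 1, trials >= 1, length(postures) >= 1,
            length(blankets) >= 1)
  grid_df <- expand.grid(
    trial = seq_len(trials),
    blanket = blankets,
    posture = postures,
    subject_id = sprintf("sub%03d", seq_len(n_subjects)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("subject_id", "posture", "blanket", "trial")]
  manifest <- tibble::as_tibble(grid_df)
  manifest$sample_id <- sprintf("%s_%s_%s_t%d", manifest$subject_id,
                                manifest$posture, manifest$blanket,
                                manifest$trial)
  manifest$coarse_label <- as.character(coarse_map(manifest$posture))
  manifest <- manifest[, c("sample_id", "subject_id", "posture",
                           "coarse_label", "blanket", "trial")]

  subject_scales <- lapply(seq_len(n_subjects), function(s) {
    withr_seed(child_seed(seed, "subject", s), {
      list(height = stats::rnorm(1, 1, 0.05),
           width = stats::rnorm(1, 1, 0.07))
    })
  })
  names(subject_scales) <- sprintf("sub%03d", seq_len(n_subjects))

  samples <- NULL
  if (materialize) {
    samples <- vector("list", nrow(manifest))
    for (k in seq_len(nrow(manifest))) {
      row <- manifest[k, ]
      phantom <- withr_seed(
        child_seed(seed, "phantom", row$subject_id, row$posture,
                   row$blanket, row$trial),
        make_phantom(row$posture, subject_scales[[row$subject_id]])
      )
      frames <- lapply(placement, function(radar) {
        withr_seed(
          child_seed(seed, "frame", row$subject_id, row$posture,
                     row$blanket, row$trial, radar$radar_id),
          simulate_frame(radar, phantom, params, blanket = row$blanket)
        )
      })
      samples[[k]] <- sample_record(
        subject_id = row$subject_id, posture = row$posture,
        blanket = row$blanket, trial = row$trial, frames = frames,
        sample_id = row$sample_id
      )
    }
    names(samples) <- manifest$sample_id
  }
  list(samples = samples, manifest = manifest)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' One labelled multi-radar sample
#'
#' @param subject_id Subject identifier.
#' @param posture Fine posture label.
#' @param blanket Blanket condition.
#' @param trial Trial number.
#' @param frames Named list of `radar_frame`, one per radar.
#' @param sample_id Optional sample identifier.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(subject_id, posture, blanket, trial, frames,
                          sample_id = NULL) {
  if (!posture %in% posture_levels()) {
    stop("unknown posture label: ", posture, call. = FALSE)
  }
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  if (length(frames) > 1 &&
      (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)) {
    stop("all frames in a sample must share n_bins and n_pulses",
         call. = FALSE)
  }
  structure(
    list(sample_id = sample_id %||%
           sprintf("%s_%s_%s_t%d", subject_id, posture, blanket, trial),
         subject_id = subject_id, posture = posture, blanket = blanket,
         trial = trial, frames = frames),
    class = "sample_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record %s> posture=%s blanket=%s trial=%d, %d radars\n",
              x$sample_id, x$posture, x$blanket, x$trial, length(x$frames)))
  invisible(x)
}
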