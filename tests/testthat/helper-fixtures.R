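# Small shared fixtures, all generated in code.

# A short-range radar: 64 bins of 1 cm (0.01 m x 64 = 0.64 m max range).
toy_radar <- function(id = "HC", position = c(5, -2), boresight = c(0, 1),
                      ...) {
  radar_spec(id, position = position, boresight = boresight,
             n_bins = 64L, bin_length = 0.01, max_range = 0.64, ...)
}

# 10 x 10 grid of 1 cm cells.
toy_grid <- function() grid_spec(origin = c(0, 0), extent = c(10, 10),
                                 cell_size = 1)

# A phantom with explicit scatterers (bypasses the posture templates).
manual_phantom <- function(scatterers, posture = "S") {
  structure(list(posture = posture, scatterers = scatterers,
                 subject_scale = list(height = 1, width = 1)),
            class = "phantom")
}

empty_phantom <- function() {
  m <- matrix(numeric(0), 0, 3,
              dimnames = list(NULL, c("x", "y", "reflectivity")))
  manual_phantom(m)
}

one_scatterer_phantom <- function(x, y, reflectivity = 1) {
  manual_phantom(matrix(c(x, y, reflectivity), 1, 3,
                        dimnames = list(NULL, c("x", "y", "reflectivity"))))
}

# Quiet simulation: no noise, no clutter, no scintillation.
quiet_params <- function(...) {
  sim_params(noise_sigma = 0, clutter_amp = 0, clutter_profile = 0,
             scintillation_sd = 0, blanket_diffuse = 0, ...)
}

# Independent brute-force echo-map oracle: re-derives floor/ceil/weights
# cell by cell with plain loops (kept free of the package's vectorised path).
srem_oracle <- function(profile_values, radar_pos, grid, d, n_bins,
                        interp = "as_printed") {
  Q <- matrix(0, grid$n_x, grid$n_y)
  for (i in seq_len(grid$n_x)) {
    for (j in seq_len(grid$n_y)) {
      cx <- grid$origin[1] + (i - 0.5) * grid$cell_size
      cy <- grid$origin[2] + (j - 0.5) * grid$cell_size
      D <- sqrt((cx - radar_pos[1])^2 + (cy - radar_pos[2])^2)
      b_small <- floor(D / d)
      b_large <- ceiling(D / d)
      if (b_large >= n_bins) next
      frac <- (D %% d) / d
      Q[i, j] <- if (interp == "as_printed") {
        profile_values[b_small + 1] * frac +
          profile_values[b_large + 1] * (1 - frac)
      } else {
        profile_values[b_small + 1] * (1 - frac) +
          profile_values[b_large + 1] * frac
      }
    }
  }
  Q
}

# Directly separable 4-class multiview fixture: each class lights up a
# different corner of the map, plus mild noise. Returns list(x, y).
corner_blob_fixture <- function(n_per_class = 10, n_views = 2, size = 16,
                                noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    corners <- list(c(4, 4), c(4, 12), c(12, 4), c(12, 12))
    n <- n_per_class * 4
    x <- array(stats::rnorm(n * n_views * size * size, 0, noise),
               c(n, n_views, size, size))
    y <- rep(coarse_levels(), each = n_per_class)
    for (k in seq_len(n)) {
      cc <- corners[[match(y[k], coarse_levels())]]
      for (v in seq_len(n_views)) {
        x[k, v, cc[1] + (-2:2), cc[2] + (-2:2)] <-
          x[k, v, cc[1] + (-2:2), cc[2] + (-2:2)] + 1
      }
    }
    list(x = x, y = factor(y, levels = coarse_levels()))
  })
}
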