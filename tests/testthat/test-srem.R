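toy_profile <- function(values) {
  intensity_profile(values, radar_id = "HC", bin_length = 0.01)
}

test_that("echo maps match an independent brute-force oracle", {
  g <- toy_grid()
  r <- toy_radar(position = c(-2, 5), boresight = c(1, 0))
  d <- r$max_range * 100 / r$n_bins
  set.seed(42)
  for (rep in 1:5) {
    prof <- toy_profile(runif(64))
    pos <- c(runif(1, -4, 0), runif(1, 0, 10))
    rr <- toy_radar(position = pos, boresight = c(1, 0))
    for (interp in c("as_printed", "corrected")) {
      got <- generate_srem(prof, rr, g, interp = interp, masked = FALSE)
      ref <- srem_oracle(prof$values, pos, g, d, 64, interp = interp)
      expect_lt(max(abs(got$values - ref)), 1e-9)
    }
  }
})

test_that("interpolation collapses at exact bin multiples and weights sum to 1", {
  # all-zero profile -> all-zero map
  g <- toy_grid()
  r <- toy_radar(position = c(5, -3))
  expect_equal(generate_srem(toy_profile(rep(0, 64)), r, g)$values,
               matrix(0, 10, 10))

  # single cell at distance exactly b*d sees profile[b] in both modes
  prof <- toy_profile(replace(rep(0, 64), 6, 1))  # 1.0 at 0-based bin 5
  g1 <- grid_spec(origin = c(0, 4), extent = c(1, 1), cell_size = 1)
  r1 <- toy_radar(position = c(0.5, -0.5), boresight = c(0, 1))  # D = 5 = 5*d
  for (interp in c("as_printed", "corrected")) {
    expect_equal(generate_srem(prof, r1, g1, interp = interp)$values[1, 1], 1)
  }

  # constant profile -> constant map on in-range cells (weights sum to 1)
  pc <- toy_profile(rep(0.7, 64))
  m <- generate_srem(pc, r, g, masked = FALSE)
  expect_true(all(abs(m$values - 0.7) < 1e-12))
})

test_that("echo-map generation is linear in the profile", {
  g <- toy_grid()
  r <- toy_radar(position = c(11, 3), boresight = c(-1, 0))
  set.seed(11)
  p <- runif(64); q <- runif(64)
  for (interp in c("as_printed", "corrected")) {
    mp <- generate_srem(toy_profile(p), r, g, interp = interp)$values
    mq <- generate_srem(toy_profile(q), r, g, interp = interp)$values
    mpq <- generate_srem(toy_profile(2 * p + 3 * q), r, g,
                         interp = interp)$values
    expect_equal(mpq, 2 * mp + 3 * mq, tolerance = 1e-9)
  }
})

test_that("masking zeroes all cells outside the azimuth sector", {
  g <- toy_grid()
  r <- toy_radar(position = c(5, -3), azimuth_half_angle = 40)
  prof <- toy_profile(rep(1, 64))
  m <- generate_srem(prof, r, g, masked = TRUE)
  sector <- azimuth_mask(r, g)
  expect_true(all(m$values[!sector] == 0))
  expect_true(all(m$values[sector] > 0))
  # unmasked map has full in-range support
  mu <- generate_srem(prof, r, g, masked = FALSE)
  expect_true(all(mu$values > 0))
})

test_that("out-of-range cells contribute zero rather than clamping", {
  # 16-bin radar: max range 0.16 m = 16 cm; far cells must be zero
  r <- radar_spec("HC", c(0.5, -0.5), c(0, 1), n_bins = 16L,
                  bin_length = 0.01, max_range = 0.16)
  g <- grid_spec(origin = c(0, 0), extent = c(1, 30), cell_size = 1)
  prof <- intensity_profile(rep(1, 16), bin_length = 0.01)
  m <- generate_srem(prof, r, g, masked = FALSE)
  D <- distance_map(r, g)   # integer distances by construction
  expect_true(all(m$values[D >= 16] == 0))
  expect_true(all(m$values[D <= 15] > 0))
})

test_that("frame accumulation is additive", {
  g <- toy_grid()
  r <- toy_radar(position = c(5, -3))
  set.seed(3)
  profs <- lapply(1:3, function(i) toy_profile(runif(64)))
  acc <- accumulate_srem(profs, r, g)
  indiv <- lapply(profs, generate_srem, radar = r, grid = g)
  expect_lt(max(abs(acc$values - Reduce(`+`, lapply(indiv, `[[`, "values")))),
            1e-9)
  one <- accumulate_srem(profs[1], r, g)
  expect_equal(one$values, indiv[[1]]$values)
  two <- accumulate_srem(profs[c(1, 1)], r, g)
  expect_equal(two$values, 2 * indiv[[1]]$values, tolerance = 1e-12)
  expect_error(accumulate_srem(list(), r, g), "at least one")
})

test_that("profile/radar mismatches are caught", {
  g <- toy_grid()
  r <- toy_radar(position = c(5, -3))
  expect_error(generate_srem(toy_profile(rep(0, 32)), r, g), "length")
  wrong_units <- intensity_profile(rep(0, 64), bin_length = 0.00643)
  expect_error(generate_srem(wrong_units, r, g), "unit mismatch")
})

test_that("view stacks honour masks, ordering and normalisation", {
  placement <- lapply(radar_slots(), function(id) {
    pos <- if (startsWith(id, "H")) c(20 + 25 * (match(id, c("HL", "HC", "HR")) - 1), -20)
           else c(-20, 15 * match(id, c("S1", "S2", "S3", "S4", "S5")) + 15)
    bore <- if (startsWith(id, "H")) c(0, 1) else c(1, 0)
    toy_radar(id, position = pos, boresight = bore)
  })
  names(placement) <- radar_slots()
  grid <- grid_spec(extent = c(90, 196), cell_size = 4)
  ds <- generate_dataset(1, postures = "S", blankets = "thin", trials = 1,
                         placement = placement,
                         params = sim_params(n_pulses = 4), seed = 2)
  s <- ds$samples[[1]]

  full <- build_view_stack(s, placement, grid)
  expect_length(full$views, 8)
  expect_identical(full$radar_ids, radar_slots())

  cfg22 <- ensemble_config(c("S3", "HC"))
  two <- build_view_stack(s, placement, grid, mask = cfg22)
  expect_length(two$views, 2)
  expect_identical(two$radar_ids, c("HC", "S3"))  # canonical order

  # normalised views live in [0, 1]
  rngs <- vapply(full$views, function(v) range(v$values), numeric(2))
  expect_true(all(rngs >= 0 & rngs <= 1))

  # a missing radar is a data error naming it
  s2 <- s; s2$frames$S3 <- NULL
  expect_error(build_view_stack(s2, placement, grid, mask = cfg22), "S3")
})

test_that("min-max normalisation of a constant map is all zeros, not NaN", {
  # alternating +/- pulses: suppression leaves them, envelope is constant 1
  vals <- matrix(rep(c(-1, 1), each = 64), 64, 2)
  fr <- radar_frame(vals, radar_id = "HC", bin_length = 0.01)
  s <- sample_record("sub001", "S", "thin", 1, frames = list(HC = fr))
  g <- grid_spec(origin = c(0, 0), extent = c(5, 5), cell_size = 1)
  pl <- list(HC = toy_radar(position = c(2.5, -1), boresight = c(0, 1),
                            azimuth_half_angle = 89))
  st <- build_view_stack(s, pl, g, masked = FALSE)
  expect_false(any(is.nan(st$views$HC$values)))
  expect_true(all(st$views$HC$values == 0))
})
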