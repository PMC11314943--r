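test_that("cell centres use the half-cell offset and round-trip to indices", {
  g <- grid_spec()
  expect_equal(unname(cell_center(g, 1, 1)), cbind(0.3215, 0.3215),
               ignore_attr = TRUE)
  g1 <- grid_spec(extent = c(20, 20), cell_size = 1)
  expect_equal(unname(cell_center(g1, 5, 10)), cbind(4.5, 9.5),
               ignore_attr = TRUE)
  expect_error(cell_center(g1, 0, 1), "out of range")
  expect_error(cell_center(g1, 1, 21), "out of range")

  # round-trip: flooring (centre - origin)/cell_size recovers the index
  g2 <- grid_spec(origin = c(-3, 2), extent = c(13, 9), cell_size = 0.7)
  ij <- expand.grid(i = seq_len(g2$n_x), j = seq_len(g2$n_y))
  ctr <- cell_center(g2, ij$i, ij$j)
  expect_equal(floor((ctr[, 1] - g2$origin[1]) / g2$cell_size) + 1, ij$i)
  expect_equal(floor((ctr[, 2] - g2$origin[2]) / g2$cell_size) + 1, ij$j)
})

test_that("default bed grid truncates to 139 x 304 cells", {
  g <- grid_spec()
  expect_identical(g$n_x, 139L)
  expect_identical(g$n_y, 304L)
})

test_that("distance_map is Euclidean, matches brute force, and is symmetric", {
  # 3-4-5 triangle: radar at origin, cell centre at (3, 4)
  g <- grid_spec(origin = c(2.5, 3.5), extent = c(1, 1), cell_size = 1)
  r <- toy_radar(position = c(0, 0))
  expect_equal(distance_map(r, g)[1, 1], 5)

  # radar coincident with a cell centre
  r0 <- toy_radar(position = c(2.5, 3.5))
  g0 <- grid_spec(origin = c(0, 0), extent = c(5, 5), cell_size = 1)
  expect_equal(distance_map(r0, g0)[3, 4], 0)

  # element-by-element brute force on a 10 x 10 grid
  g10 <- toy_grid()
  r10 <- toy_radar(position = c(-2.3, 4.7))
  D <- distance_map(r10, g10)
  ref <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    ctr <- cell_center(g10, i, j)
    ref[i, j] <- sqrt(sum((ctr - c(-2.3, 4.7))^2))
  }
  expect_equal(D, ref, tolerance = 1e-12)

  # metric symmetry: swapping radar and cell positions preserves distance
  p <- c(1.5, 2.5); q <- c(7.5, 8.5)
  gq <- grid_spec(origin = q - 0.5, extent = c(1, 1), cell_size = 1)
  gp <- grid_spec(origin = p - 0.5, extent = c(1, 1), cell_size = 1)
  expect_equal(distance_map(toy_radar(position = p), gq)[1, 1],
               distance_map(toy_radar(position = q), gp)[1, 1])

  # 3d mode lengthens slant ranges by the height offset
  rz <- toy_radar(position = c(0, 0), z = 30)
  expect_equal(distance_map(rz, g, mode = "3d")[1, 1], sqrt(25 + 900))
})

test_that("azimuth mask honours the field-of-view boundary", {
  # radar below a single-cell grid, boresight +y: cell dead ahead
  g <- grid_spec(origin = c(-0.5, 9.5), extent = c(1, 1), cell_size = 1)
  r <- toy_radar(position = c(0, 0), boresight = c(0, 1))
  expect_true(azimuth_mask(r, g)[1, 1])

  # a cell at a controlled angle off boresight
  cell_at_angle <- function(theta_deg, half_angle) {
    rad <- theta_deg * pi / 180
    pos <- 10 * c(sin(rad), cos(rad))
    gg <- grid_spec(origin = pos - 0.5, extent = c(1, 1), cell_size = 1)
    rr <- toy_radar(position = c(0, 0), boresight = c(0, 1),
                    azimuth_half_angle = half_angle)
    azimuth_mask(rr, gg)[1, 1]
  }
  expect_true(cell_at_angle(64, 65))
  expect_false(cell_at_angle(66, 65))   # just past the +/-65 degree sector
  expect_false(cell_at_angle(90, 65))
  expect_true(cell_at_angle(89, 90))    # half-angle 90: forward half-plane

  # monotonicity: shrinking the half-angle never adds cells
  g10 <- toy_grid()
  prev <- NULL
  for (ha in c(90, 65, 40, 15)) {
    m <- azimuth_mask(toy_radar(position = c(5, -3), boresight = c(0, 1),
                                azimuth_half_angle = ha), g10)
    if (!is.null(prev)) expect_true(all(prev | !m))
    prev <- m
  }

  # radar's own cell is defined inside the sector
  rin <- toy_radar(position = c(4.5, 4.5), boresight = c(1, 0))
  expect_true(azimuth_mask(rin, g10)[5, 5])
})

test_that("default placement has 8 radars with bench offsets and spacing", {
  pl <- default_placement()
  expect_length(pl, 8)
  expect_identical(names(pl), radar_slots())
  side_y <- vapply(pl[c("S1", "S2", "S3", "S4", "S5")],
                   function(r) r$position[2], numeric(1))
  expect_equal(unname(diff(side_y)), rep(15, 4))       # 15 cm spacing
  for (id in c("S1", "S2", "S3", "S4", "S5")) {
    expect_equal(pl[[id]]$position[1], -20)            # 20 cm off the edge
    expect_equal(pl[[id]]$boresight, c(1, 0))
  }
  for (id in c("HL", "HC", "HR")) {
    expect_equal(pl[[id]]$position[2], -20)
    expect_equal(pl[[id]]$boresight, c(0, 1))
  }
  pr <- default_placement(side = "right")
  expect_equal(pr$S3$position[1], 110)
  expect_equal(pr$S3$boresight, c(-1, 0))
})

test_that("radar_spec enforces its invariants", {
  expect_error(radar_spec("A", c(0, 0), c(0, 0)), "nonzero")
  expect_error(radar_spec("A", c(0, 0), c(0, 1), azimuth_half_angle = 0),
               "0, 90")
  expect_error(radar_spec("A", c(0, 0), c(0, 1), n_bins = 100,
                          bin_length = 0.01, max_range = 9.87),
               "within 1%")
  r <- radar_spec("A", c(0, 0), c(0, 2))
  expect_equal(sqrt(sum(r$boresight^2)), 1)  # boresight normalised
})

test_that("geometry configs round-trip through JSON", {
  pl <- default_placement()
  g <- grid_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry_config(pl, g, path)
  back <- read_geometry_config(path)
  expect_identical(names(back$placement), radar_slots())
  expect_equal(back$grid$n_x, g$n_x)
  expect_equal(back$placement$S4$position, pl$S4$position)
  expect_equal(back$placement$HL$bin_length, pl$HL$bin_length)
})
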