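#' Canonical radar slot order
#'
#' The eight radar positions around the bed, in the canonical order used by
#' view stacks and ensemble masks: three headboard radars (left, centre,
#' right), then the five side radars from cranial to caudal.
#'
#' @return Character vector of the eight radar identifiers.
#' @export
radar_slots <- function() {
  c("HL", "HC", "HR", "S1", "S2", "S3", "S4", "S5")
}

#' Radar specification
#'
#' Describes one IR-UWB radar: its pose in the bed frame and its acquisition
#' parameters. Geometry is in centimetres; `bin_length` and `max_range` are
#' in metres, matching the hardware convention. The defaults reproduce the
#' Xethru X4M03 long-frame parameterisation: 1536 range bins over 9.87 m,
#' i.e. a bin length of 0.00643 m, with a +/- 65 degree azimuth field of view.
#'
#' @param radar_id One of `radar_slots()`, or a custom identifier.
#' @param position Numeric `(x, y)` position in cm in the bed frame
#'   (origin at the headboard-left bed corner, x across the 90 cm width,
#'   y along the 196 cm length).
#' @param boresight Unit(ish) vector in the bed plane giving the antenna
#'   pointing direction; it is normalised internally.
#' @param azimuth_half_angle Half-width of the azimuth field of view,
#'   degrees, in (0, 90].
#' @param bin_length Range-bin length in metres.
#' @param n_bins Number of fast-time range bins per pulse.
#' @param max_range Maximum unambiguous range in metres; must agree with
#'   `bin_length * n_bins` to within 1%.
#' @param frame_rate Pulse frame rate in Hz.
#' @param z Optional height of the antenna above the bed plane, cm; used
#'   only by the `"3d"` distance mode.
#' @return An object of class `radar_spec`.
#' @examples
#' r <- radar_spec("HC", position = c(45, -20), boresight = c(0, 1))
#' r$bin_length * r$n_bins  # ~ max_range
#' @export
radar_spec <- function(radar_id,
                       position,
                       boresight,
                       azimuth_half_angle = 65,
                       bin_length = 0.00643,
                       n_bins = 1536L,
                       max_range = 9.87,
                       frame_rate = 20,
                       z = NULL) {
  stopifnot(is.character(radar_id), length(radar_id) == 1L)
  position <- as.numeric(position)
  if (length(position) != 2L || !all(is.finite(position))) {
    stop("`position` must be a finite (x, y) pair in cm", call. = FALSE)
  }
  boresight <- as.numeric(boresight)
  if (length(boresight) != 2L || sqrt(sum(boresight^2)) == 0) {
    stop("`boresight` must be a nonzero (x, y) vector", call. = FALSE)
  }
  boresight <- boresight / sqrt(sum(boresight^2))
  if (!(azimuth_half_angle > 0 && azimuth_half_angle <= 90)) {
    stop("`azimuth_half_angle` must lie in (0, 90] degrees", call. = FALSE)
  }
  if (bin_length <= 0) stop("`bin_length` must be positive", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  if (abs(bin_length * n_bins - max_range) > 0.01 * max_range) {
    stop("`bin_length * n_bins` must equal `max_range` within 1%",
         call. = FALSE)
  }
  structure(
    list(
      radar_id = radar_id,
      position = position,
      boresight = boresight,
      azimuth_half_angle = azimuth_half_angle,
      bin_length = bin_length,
      n_bins = n_bins,
      max_range = max_range,
      frame_rate = frame_rate,
      z = if (is.null(z)) NULL else as.numeric(z)
    ),
    class = "radar_spec"
  )
}

#' @export
print.radar_spec <- function(x, ...) {
  cat(sprintf(
    "<radar_spec %s> pos=(%.1f, %.1f) cm, boresight=(%.2f, %.2f), fov=+/-%g deg, %d bins x %.5f m\n",
    x$radar_id, x$position[1], x$position[2],
    x$boresight[1], x$boresight[2],
    x$azimuth_half_angle, x$n_bins, x$bin_length
  ))
  invisible(x)
}

#' Bed-grid specification
#'
#' A regular grid covering the bed surface, on which Spatial Radar Echo Maps
#' are evaluated. The defaults tile the 90 x 196 cm bed with cells whose side
#' equals the radar bin length expressed in cm (0.643 cm), giving a
#' 139 x 304 grid. Cell counts are truncated (`int`) so the grid never
#' extends past the stated extent.
#'
#' @param origin `(x0, y0)` of the grid corner, cm.
#' @param extent `(x, y)` size of the gridded region, cm.
#' @param cell_size Cell side, cm.
#' @return An object of class `grid_spec` with fields `n_x`, `n_y`.
#' @examples
#' g <- grid_spec()
#' c(g$n_x, g$n_y)  # 139 304
#' @export
grid_spec <- function(origin = c(0, 0), extent = c(90, 196),
                      cell_size = 0.643) {
  origin <- as.numeric(origin)
  extent <- as.numeric(extent)
  stopifnot(length(origin) == 2L, length(extent) == 2L)
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (any(extent <= 0)) stop("`extent` must be positive", call. = FALSE)
  structure(
    list(
      origin = origin,
      extent = extent,
      cell_size = cell_size,
      n_x = as.integer(extent[1] / cell_size),
      n_y = as.integer(extent[2] / cell_size)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.3f cm over (%g, %g)-(%g, %g) cm\n",
              x$n_x, x$n_y, x$cell_size,
              x$origin[1], x$origin[2],
              x$origin[1] + x$extent[1], x$origin[2] + x$extent[2]))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' Maps 1-based grid indices to the physical centre of the cell. The
#' cell-centre (not corner) convention is used throughout distance and
#' azimuth evaluation.
#'
#' @param grid A `grid_spec`.
#' @param i Column index along the bed width, 1..n_x.
#' @param j Row index along the bed length, 1..n_y. `i` and `j` may be
#'   vectors of equal length.
#' @return A two-column matrix of `(x, y)` centres in cm.
#' @export
cell_center <- function(grid, i, j) {
  stopifnot(inherits(grid, "grid_spec"))
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > grid$n_x) || any(j < 1L | j > grid$n_y)) {
    stop("cell index out of range", call. = FALSE)
  }
  cbind(
    x = grid$origin[1] + (i - 0.5) * grid$cell_size,
    y = grid$origin[2] + (j - 0.5) * grid$cell_size
  )
}

# Coordinate vectors of all cell centres along each axis.
grid_axes <- function(grid) {
  list(
    x = grid$origin[1] + (seq_len(grid$n_x) - 0.5) * grid$cell_size,
    y = grid$origin[2] + (seq_len(grid$n_y) - 0.5) * grid$cell_size
  )
}

#' Per-cell distance from a radar
#'
#' Euclidean distance from every grid-cell centre to the radar position, in
#' cm. The `"planar"` mode (default) works strictly in the bed plane; the
#' `"3d"` mode additionally includes the antenna's height offset above the
#' bed plane (the `z` field of the radar spec), lengthening all slant ranges.
#'
#' @param radar A `radar_spec`.
#' @param grid A `grid_spec`.
#' @param mode `"planar"` or `"3d"`.
#' @return An `n_x` x `n_y` numeric matrix of distances in cm.
#' @export
distance_map <- function(radar, grid, mode = c("planar", "3d")) {
  stopifnot(inherits(radar, "radar_spec"), inherits(grid, "grid_spec"))
  mode <- match.arg(mode)
  ax <- grid_axes(grid)
  dx2 <- (ax$x - radar$position[1])^2
  dy2 <- (ax$y - radar$position[2])^2
  d2 <- outer(dx2, dy2, `+`)
  if (mode == "3d") {
    z <- if (is.null(radar$z)) 0 else radar$z
    d2 <- d2 + z^2
  }
  sqrt(d2)
}

#' Azimuth sector mask
#'
#' Marks the grid cells that fall inside the radar's azimuth field of view:
#' a cell is `TRUE` iff the angle between the boresight and the vector from
#' the radar to the cell centre is at most `azimuth_half_angle`. A cell
#' coincident with the radar (zero direction vector) is defined `TRUE`.
#'
#' @inheritParams distance_map
#' @return An `n_x` x `n_y` logical matrix.
#' @export
azimuth_mask <- function(radar, grid) {
  stopifnot(inherits(radar, "radar_spec"), inherits(grid, "grid_spec"))
  ax <- grid_axes(grid)
  dx <- ax$x - radar$position[1]
  dy <- ax$y - radar$position[2]
  nx <- grid$n_x; ny <- grid$n_y
  # cos(angle) = (v . boresight) / |v|; boresight is unit length
  dot <- outer(dx * radar$boresight[1], dy * radar$boresight[2], `+`)
  nrm <- sqrt(outer(dx^2, dy^2, `+`))
  cosang <- ifelse(nrm == 0, 1, dot / pmax(nrm, .Machine$double.eps))
  cosang >= cos(radar$azimuth_half_angle * pi / 180) - 1e-12
}

#' Default eight-radar placement
#'
#' The baseline bench layout: three headboard radars (HL, HC, HR) facing
#' along +y into the bed, and five side radars (S1..S5, cranial to caudal)
#' on the left long edge facing along +x. All radars sit 20 cm outside the
#' nearest bed edge; side radars are spaced 15 cm apart over the upper body
#' (y = 30..90 cm), head radars at x = 20, 45, 70 cm. Side antennas are
#' mounted 18 cm and head antennas 48 cm above the bed plane (stored in `z`,
#' used only in 3d distance mode).
#'
#' Absolute coordinates are bench assumptions: the hardware layout fixes the
#' edge offsets and spacings but not an origin.
#'
#' @param side `"left"` or `"right"`: which long edge carries S1..S5.
#' @param ... Passed on to [radar_spec()] (e.g. `n_bins`, `max_range`).
#' @return Named list of eight `radar_spec`, in canonical slot order.
#' @export
default_placement <- function(side = c("left", "right"), ...) {
  side <- match.arg(side)
  head_x <- c(HL = 20, HC = 45, HR = 70)
  specs <- list()
  for (id in names(head_x)) {
    specs[[id]] <- radar_spec(id, position = c(head_x[[id]], -20),
                              boresight = c(0, 1), z = 48, ...)
  }
  side_y <- c(S1 = 30, S2 = 45, S3 = 60, S4 = 75, S5 = 90)
  sx <- if (side == "left") -20 else 110
  sbore <- if (side == "left") c(1, 0) else c(-1, 0)
  for (id in names(side_y)) {
    specs[[id]] <- radar_spec(id, position = c(sx, side_y[[id]]),
                              boresight = sbore, z = 18, ...)
  }
  specs[radar_slots()]
}

#' Write / read a geometry configuration
#'
#' Radar and grid specifications serialise to a single JSON file. Keys
#' mirror the constructor arguments; geometry is in cm, `bin_length` and
#' `max_range` in metres.
#'
#' @param placement Named list of `radar_spec`.
#' @param grid A `grid_spec`.
#' @param path File path to write / read.
#' @return `write_geometry_config` returns `path` invisibly;
#'   `read_geometry_config` returns `list(placement=, grid=)`.
#' @export
write_geometry_config <- function(placement, grid, path) {
  stopifnot(inherits(grid, "grid_spec"))
  radars <- lapply(placement, function(r) {
    stopifnot(inherits(r, "radar_spec"))
    out <- unclass(r)
    out[!vapply(out, is.null, logical(1))]
  })
  cfg <- list(
    schema = "bedradar-geometry/1",
    grid = list(origin = grid$origin, extent = grid$extent,
                cell_size = grid$cell_size),
    radars = radars
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(cfg$schema, "bedradar-geometry/1")) {
    stop("unrecognised geometry config schema: ", cfg$schema, call. = FALSE)
  }
  grid <- grid_spec(origin = cfg$grid$origin, extent = cfg$grid$extent,
                    cell_size = cfg$grid$cell_size)
  placement <- lapply(cfg$radars, function(r) {
    radar_spec(r$radar_id, position = r$position, boresight = r$boresight,
               azimuth_half_angle = r$azimuth_half_angle,
               bin_length = r$bin_length, n_bins = r$n_bins,
               max_range = r$max_range, frame_rate = r$frame_rate,
               z = r$z)
  })
  names(placement) <- vapply(placement, `[[`, character(1), "radar_id")
  list(placement = placement, grid = grid)
}
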