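# Planar antenna array geometry, imaging grids and propagation media.
#
# Internal unit conventions (everywhere in the package):
#   lengths in millimetres, times in nanoseconds, frequencies in gigahertz.
# Coordinate frame: origin at one corner of the antenna mounting sheet,
# x to the right, y up (both in-plane), z pointing from the antenna plane
# down into the phantom. The antenna plane is z = 0.

#' Speed of light in vacuum, mm/ns
#'
#' @keywords internal
C_MM_NS <- 299.792458

#' Construct an antenna element
#'
#' @param id Integer label (1-based).
#' @param position Numeric length-3 position in mm; the z component must be 0
#'   (all antennas lie in the z = 0 plane).
#' @param orientation Length-2 in-plane unit vector giving the patch long-axis
#'   direction. Normalized internally.
#' @return An object of class `mwi_element`.
#' @export
antenna_element <- function(id, position, orientation = c(1, 0)) {
  stopifnot(length(position) == 3, length(orientation) == 2)
  if (abs(position[3]) > 1e-9) {
    stop("antenna positions must lie in the z = 0 plane")
  }
  n <- sqrt(sum(orientation^2))
  if (n == 0) stop("orientation must be a nonzero vector")
  structure(
    list(id = as.integer(id), position = as.numeric(position),
         orientation = as.numeric(orientation) / n),
    class = "mwi_element"
  )
}

#' Construct an antenna array
#'
#' @param elements List of [antenna_element()] objects.
#' @param extent Length-2 numeric, (width, height) of the mounting sheet, mm.
#' @param min_spacing Minimum allowed center-to-center spacing in mm. Elements
#'   closer than this interact electromagnetically and are rejected.
#' @return An object of class `mwi_array` with components `elements`,
#'   `extent` and `M` (the element count).
#' @export
antenna_array <- function(elements, extent = c(300, 300), min_spacing = 25) {
  ids <- vapply(elements, function(e) e$id, integer(1))
  if (anyDuplicated(ids)) stop("antenna ids must be unique")
  pos <- antenna_positions_list(elements)
  if (any(pos[, 1] < 0 | pos[, 1] > extent[1] |
          pos[, 2] < 0 | pos[, 2] > extent[2])) {
    stop("all antennas must lie within the sheet extent")
  }
  if (length(elements) > 1) {
    dmin <- min(stats::dist(pos[, 1:2, drop = FALSE]))
    if (dmin < min_spacing - 1e-9) {
      stop(sprintf("antenna spacing %.1f mm below the %.0f mm minimum",
                   dmin, min_spacing))
    }
  }
  structure(
    list(elements = elements, extent = as.numeric(extent),
         M = length(elements)),
    class = "mwi_array"
  )
}

antenna_positions_list <- function(elements) {
  t(vapply(elements, function(e) e$position, numeric(3)))
}

#' Antenna positions as a matrix
#'
#' @param array An `mwi_array`.
#' @return M x 3 numeric matrix of positions in mm.
#' @export
antenna_positions <- function(array) {
  antenna_positions_list(array$elements)
}

#' @export
print.mwi_array <- function(x, ...) {
  cat(sprintf("Planar antenna array: %d elements on a %g x %g mm sheet\n",
              x$M, x$extent[1], x$extent[2]))
  invisible(x)
}

#' Default 16-element planar array
#'
#' Builds the reference layout: 16 monopole antennas on a 300 x 300 mm
#' methacrylate sheet, four rows of four antennas with alternate rows
#' staggered in x and alternating orthogonal patch orientations, equispaced
#' over the measurement area with all pairwise spacings at or above the
#' 25 mm electromagnetic-interaction minimum. Elements are numbered
#' column-major (by increasing x, then increasing y) so that vertical runs
#' of antennas carry consecutive labels, matching the longitudinal (y)
#' orientation of the aorta in the intended application.
#'
#' The hardware coordinates of a physical array are not uniquely determined
#' by this convention; measured positions can be supplied through
#' [read_array_layout()] instead.
#'
#' @return An `mwi_array` with 16 elements.
#' @export
build_default_array <- function() {
  ys <- c(60, 120, 180, 240)
  xs_plain <- c(60, 120, 180, 240)   # rows 1 and 3
  xs_stag <- c(90, 150, 210, 270)    # rows 2 and 4, staggered +30 mm
  pts <- NULL
  for (r in seq_along(ys)) {
    xs <- if (r %% 2 == 1) xs_plain else xs_stag
    pts <- rbind(pts, cbind(xs, ys[r]))
  }
  # column-major labeling: sort by x then y
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  elements <- lapply(seq_len(nrow(pts)), function(i) {
    orient <- if (i %% 2 == 1) c(0, 1) else c(1, 0)  # alternate orthogonal
    antenna_element(i, c(pts[i, 1], pts[i, 2], 0), orient)
  })
  antenna_array(elements, extent = c(300, 300))
}

#' Read an array layout from CSV
#'
#' Expects columns `id,x_mm,y_mm,orient_x,orient_y`.
#'
#' @param path CSV file path.
#' @param extent Sheet extent in mm.
#' @return An `mwi_array`.
#' @export
read_array_layout <- function(path, extent = c(300, 300)) {
  df <- utils::read.csv(path)
  need <- c("id", "x_mm", "y_mm", "orient_x", "orient_y")
  if (!all(need %in% names(df))) {
    stop("layout file must have columns ", paste(need, collapse = ","))
  }
  elements <- lapply(seq_len(nrow(df)), function(i) {
    antenna_element(df$id[i], c(df$x_mm[i], df$y_mm[i], 0),
                    c(df$orient_x[i], df$orient_y[i]))
  })
  antenna_array(elements, extent = extent)
}

#' Write an array layout to CSV
#'
#' @param array An `mwi_array`.
#' @param path Output CSV path.
#' @export
write_array_layout <- function(array, path) {
  pos <- antenna_positions(array)
  ori <- t(vapply(array$elements, function(e) e$orientation, numeric(2)))
  df <- data.frame(
    id = vapply(array$elements, function(e) e$id, integer(1)),
    x_mm = pos[, 1], y_mm = pos[, 2],
    orient_x = ori[, 1], orient_y = ori[, 2]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Propagation medium
#'
#' @param eps_r Real part of the relative dielectric permittivity (>= 1).
#' @param sigma Conductivity in S/m (>= 0).
#' @return An `mwi_medium` object.
#' @export
medium <- function(eps_r = 1, sigma = 0) {
  if (eps_r < 1) stop("eps_r must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(eps_r = eps_r, sigma = sigma), class = "mwi_medium")
}

#' Round-trip propagation distance
#'
#' Monostatic convention: the same antenna transmits and receives, so the
#' path length is twice the straight-line distance between the antenna and
#' the focal point.
#'
#' @param antenna An `mwi_element` (or a length-3 position vector).
#' @param point Length-3 focal point, mm, with z >= 0.
#' @return Round-trip distance in mm.
#' @export
round_trip_distance <- function(antenna, point) {
  p <- if (inherits(antenna, "mwi_element")) antenna$position else antenna
  stopifnot(length(point) == 3)
  2 * sqrt(sum((p - point)^2))
}

#' Imaging grid on a plane parallel to the antennas
#'
#' @param extent Length-2 (width, height) of the imaged area, mm.
#' @param spacing Pixel pitch, mm (> 0).
#' @param depth Depth z of the reconstruction plane below the antenna
#'   plane, mm (>= 0).
#' @return An `mwi_grid` with `x`, `y` coordinate vectors, `depth`,
#'   `spacing`, and the full point set accessible via [grid_points()].
#' @export
build_grid <- function(extent, spacing, depth) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (depth < 0) stop("grid depth must be >= 0")
  structure(
    list(x = seq(0, extent[1], by = spacing),
         y = seq(0, extent[2], by = spacing),
         depth = depth, spacing = spacing),
    class = "mwi_grid"
  )
}

#' Grid points as a matrix
#'
#' Points are ordered x-fastest (column-major over the `nx` x `ny` raster),
#' so `matrix(values, nrow = length(grid$x))` reshapes a per-point vector
#' back onto the raster with rows indexing x.
#'
#' @param grid An `mwi_grid`.
#' @return (nx*ny) x 3 matrix of (x, y, depth) coordinates in mm.
#' @export
grid_points <- function(grid) {
  g <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
  cbind(g$x, g$y, grid$depth)
}

#' @export
print.mwi_grid <- function(x, ...) {
  cat(sprintf("Imaging grid: %d x %d points, %g mm pitch, depth %g mm\n",
              length(x$x), length(x$y), x$spacing, x$depth))
  invisible(x)
}
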