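# Cell geometry: 2D outlines (rod = stadium, spheroplast = circle) in the
# focal plane. All coordinates in micrometres.

#' Cell geometry for sheath simulations
#'
#' Describes the 2D outline of an imaged cell: a spheroplast (circle of the
#' given diameter) or a rod (stadium: a rectangle of length `length_um` minus
#' `diameter_um`, capped by two semicircles of diameter `diameter_um`, so the
#' pole-to-pole length is `length_um`). Sheaths are simulated and imaged in a
#' single focal plane, so the geometry is two-dimensional.
#'
#' @param shape `"spheroplast"` or `"rod"`.
#' @param diameter_um Cell diameter (circle diameter or rod width), in um.
#' @param length_um Rod pole-to-pole length in um; must be >= `diameter_um`.
#'   Ignored for spheroplasts.
#' @param center_um Numeric length-2 centre of the cell, um. Default `c(0, 0)`.
#'
#' @return An object of class `cell_geometry`.
#' @examples
#' g <- cell_geometry("spheroplast", diameter_um = 4)
#' chord_length(g, membrane_point(g, pi), c(1, 0))  # full diameter: 4 um
#' @export
cell_geometry <- function(shape = c("spheroplast", "rod"), diameter_um,
                          length_um = NULL, center_um = c(0, 0)) {
  shape <- match.arg(shape)
  if (!is.numeric(diameter_um) || length(diameter_um) != 1 || diameter_um <= 0)
    stop("`diameter_um` must be a single positive number")
  if (shape == "rod") {
    if (is.null(length_um) || !is.numeric(length_um) || length_um < diameter_um)
      stop("rod geometry requires `length_um` >= `diameter_um`")
  } else {
    length_um <- diameter_um
  }
  stopifnot(is.numeric(center_um), length(center_um) == 2)
  structure(
    list(shape = shape, diameter_um = diameter_um, length_um = length_um,
         center_um = as.numeric(center_um)),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %s, diameter %.2f um", x$shape, x$diameter_um))
  if (x$shape == "rod") cat(sprintf(", length %.2f um", x$length_um))
  cat(sprintf(", centre (%.2f, %.2f)\n", x$center_um[1], x$center_um[2]))
  invisible(x)
}

#' Test whether points lie inside a cell
#'
#' @param geometry A [cell_geometry()].
#' @param x,y Numeric vectors of coordinates, um.
#' @return Logical vector.
#' @export
inside_cell <- function(geometry, x, y) {
  cx <- geometry$center_um[1]
  cy <- geometry$center_um[2]
  r <- geometry$diameter_um / 2
  if (geometry$shape == "spheroplast") {
    (x - cx)^2 + (y - cy)^2 <= r^2
  } else {
    # stadium with long axis along x
    h <- geometry$length_um / 2 - r      # half-length of the straight segment
    dx <- pmax(abs(x - cx) - h, 0)
    dx^2 + (y - cy)^2 <= r^2
  }
}

#' Point on the cell membrane at a given polar angle
#'
#' Returns the boundary point reached from the cell centre along the direction
#' `(cos(angle), sin(angle))`. Used to place sheath baseplates on the membrane.
#'
#' @param geometry A [cell_geometry()].
#' @param angle_rad Polar angle in radians.
#' @return Numeric length-2 point, um.
#' @export
membrane_point <- function(geometry, angle_rad) {
  u <- c(cos(angle_rad), sin(angle_rad))
  if (geometry$shape == "spheroplast")
    return(geometry$center_um + (geometry$diameter_um / 2) * u)
  # bisection along the ray from the centre (shape is convex)
  lo <- 0
  hi <- geometry$length_um   # outside for any direction
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    p <- geometry$center_um + mid * u
    if (inside_cell(geometry, p[1], p[2])) lo <- mid else hi <- mid
  }
  geometry$center_um + ((lo + hi) / 2) * u
}

#' Chord length available from a membrane anchor along a direction
#'
#' The maximal sheath length permitted by the cell: the distance from `anchor`
#' to the point where the ray `anchor + t * direction` exits the cell. Any
#' chord is bounded by the maximal caliper diameter of the cell.
#'
#' @param geometry A [cell_geometry()].
#' @param anchor_um Numeric length-2 point on (or inside) the membrane, um.
#' @param direction Numeric length-2 direction (need not be normalized).
#' @return Chord length in um.
#' @export
chord_length <- function(geometry, anchor_um, direction) {
  u <- direction / sqrt(sum(direction^2))
  eps <- 1e-6
  p0 <- anchor_um + eps * u
  if (!inside_cell(geometry, p0[1], p0[2])) return(0)
  lo <- eps
  hi <- geometry$length_um + geometry$diameter_um  # certainly outside
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    p <- anchor_um + mid * u
    if (inside_cell(geometry, p[1], p[2])) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Logical mask of pixels whose centres fall inside the cell.
# origin_um: image-plane coordinate of the (0,0) corner of pixel [1,1];
# pixel [i,j] centre is origin + ((j-0.5), (i-0.5)) * px_um.
cell_pixel_mask <- function(geometry, nrow, ncol, px_um, origin_um) {
  xs <- origin_um[1] + (seq_len(ncol) - 0.5) * px_um
  ys <- origin_um[2] + (seq_len(nrow) - 0.5) * px_um
  xg <- matrix(xs, nrow, ncol, byrow = TRUE)
  yg <- matrix(ys, nrow, ncol)
  matrix(inside_cell(geometry, as.numeric(xg), as.numeric(yg)), nrow, ncol)
}
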