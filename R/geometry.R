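# Minimal planar geometry primitives used by the rasteriser and the vector
# readers. All coordinates are planar metric (meters); rings are 2-column
# matrices of vertices, stored open (first vertex not repeated).

#' Repair a polygon ring
#'
#' Drops repeated consecutive vertices and a closing vertex equal to the
#' first, then validates that the result is a usable ring: at least three
#' distinct vertices, finite coordinates and non-zero area. Degenerate rings
#' that cannot be repaired this way raise a geometry error.
#'
#' @param ring numeric matrix with two columns (x, y).
#' @return the repaired open ring (2-column matrix).
#' @keywords internal
repair_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || !all(is.finite(ring))) {
    stop("geometry error: ring must be a finite 2-column coordinate matrix", call. = FALSE)
  }
  n <- nrow(ring)
  if (n > 1 && all(ring[n, ] == ring[1, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3 || abs(polygon_area(ring)) <= 0) {
    stop("geometry error: degenerate polygon ring (fewer than 3 distinct vertices or zero area)",
         call. = FALSE)
  }
  ring
}

#' Signed area of a ring (shoelace formula)
#' @param ring open 2-column coordinate matrix.
#' @return signed area in square meters (positive if counter-clockwise).
#' @keywords internal
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area-weighted centroid of a ring
#' @param ring open 2-column coordinate matrix.
#' @return numeric length-2 vector (x, y).
#' @keywords internal
polygon_centroid <- function(ring) {
  a <- polygon_area(ring)
  if (abs(a) < 1e-12) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Point-in-polygon test, boundary inclusive
#'
#' Even-odd ray casting, vectorised over query points. Points lying exactly
#' on a ring edge (within an absolute tolerance of 1e-9 m) count as inside,
#' which is the deterministic tie rule used for cell-center membership.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param ring open 2-column coordinate matrix.
#' @return logical vector, TRUE where (px, py) is inside or on the ring.
#' @keywords internal
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[j, 1]; y1 <- ring[j, 2]
    x2 <- ring[i, 1]; y2 <- ring[i, 2]
    # edge crossing of the horizontal ray to +infinity
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- which(crosses)[px[crosses] < xint]
      inside[flip] <- !inside[flip]
    }
    # on-segment check (cross product ~ 0 and within the segment bbox)
    cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seglen <- max(abs(x2 - x1), abs(y2 - y1), 1)
    on <- abs(cr) <= 1e-9 * seglen &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    boundary <- boundary | on
    j <- i
  }
  inside | boundary
}
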