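# Geometric primitives used by the measure and feature layers.

# Cap used in place of an infinite slope when the two points share an x
# coordinate; keeps feature vectors finite for pathological inputs.
SLOPE_CAP <- 1e6

#' Angle between two points
#'
#' Angle of the segment from `pb` to `pa` computed as
#' `atan2(dx, dy) * 180 / pi` with `dx = pa_x - pb_x`, `dy = pa_y - pb_y`.
#' Note the x-difference is the FIRST argument of `atan2`: a horizontally
#' aligned pair yields +/-90 degrees under this convention, and the absolute
#' angle used by the asymmetry features deviates from 90 as one endpoint
#' rises or drops relative to the other.  Coincident points return 0 by
#' convention.
#'
#' @param pa,pb Length-2 numeric points (x, y).
#' @param convention `"atan2_xy"` (the default, x-difference first) or
#'   `"atan2_yx"` (conventional mathematical angle) for sensitivity analysis.
#' @return Angle in degrees in (-180, 180].
#' @export
angle_between <- function(pa, pb, convention = c("atan2_xy", "atan2_yx")) {
  convention <- match.arg(convention)
  dx <- pa[[1]] - pb[[1]]; dy <- pa[[2]] - pb[[2]]
  if (dx == 0 && dy == 0) return(0)
  if (convention == "atan2_xy") atan2(dx, dy) * 180 / pi
  else atan2(dy, dx) * 180 / pi
}

#' Slope between two points
#'
#' `(pa_y - pb_y) / (pa_x - pb_x)`.  A vertical pair (equal x, different y)
#' returns the capped sentinel `+/-1e6` with the sign of the y-difference;
#' coincident points return 0.
#'
#' @param pa,pb Length-2 numeric points.
#' @return Dimensionless slope.
#' @export
slope_between <- function(pa, pb) {
  dy <- pa[[2]] - pb[[2]]; dx <- pa[[1]] - pb[[1]]
  if (dx == 0) return(if (dy == 0) 0 else sign(dy) * SLOPE_CAP)
  dy / dx
}

#' Euclidean distance between two points
#'
#' @param pa,pb Length-2 numeric points.
#' @return Non-negative distance in the input units (pixels).
#' @export
euclidean <- function(pa, pb) {
  sqrt((pa[[1]] - pb[[1]])^2 + (pa[[2]] - pb[[2]])^2)
}

#' Perimeter of a closed shape
#'
#' Sum of the consecutive segment lengths of an ordered point list plus the
#' closing segment from the last point back to the first.
#'
#' @param points Numeric n x 2 matrix, n >= 3, vertices in order.
#' @return Perimeter in input units.
#' @export
closed_perimeter <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop_invalid("a closed shape needs at least 3 points, got %d", nrow(points))
  assert_finite_matrix(points, "shape points")
  nxt <- points[c(2:nrow(points), 1L), , drop = FALSE]
  sum(sqrt(rowSums((points - nxt)^2)))
}

# max(a/b, b/a): left/right balance ratio, >= 1, == 1 iff a == b.
ratio_max <- function(a, b) max(a / b, b / a)
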