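# Landmark containers, 68->51 selection, and rigid alignment.
#
# Coordinate convention (used everywhere in the package): image pixels with
# the origin at the top-left corner and y increasing DOWNWARD.  "Raising" a
# facial element therefore decreases its y coordinate.  "Left" means the left
# side of the image (smaller x), which is the subject's right side.

# ---------------------------------------------------------------------------
# 68 -> 51 reindexing.
#
# The 68-point shape-predictor layout (1-based): 1-17 jaw contour, 18-22 left
# eyebrow (outer->inner), 23-27 right eyebrow (inner->outer), 28-31 nose
# bridge (31 = tip), 32-36 nostril row (left->right, 34 = nose base on the
# midline), 37-42 left eye (37 outer corner, 38/39 upper lid, 40 inner
# corner, 41/42 lower lid), 43-48 right eye (43 inner corner, 44/45 upper
# lid, 46 outer corner, 47/48 lower lid), 49-60 outer lip (49 left corner,
# 52 top-mid, 55 right corner, 58 bottom-mid), 61-68 inner lip.
#
# The 17 jaw points are dropped from the primary set; three of them are kept
# as named auxiliary boundary references (chin and the two outermost jaw
# points) so head-width and mouth-to-chin measures stay computable.
#
# Reindexed P0..P50 (0-based):
#   P0-P4   left eyebrow outer->inner        (68: 18-22)
#   P5-P9   right eyebrow inner->outer       (68: 23-27)   P9 = right outer
#   P10-P15 left eye from outer corner       (68: 37-42)   P10 = left outer
#   P16-P21 right eye from inner corner      (68: 43-48)   P19 = right outer
#   P22     nose base, midline               (68: 34)
#   P23-P25 nostrils: left, mid-left, mid-right (68: 32, 33, 35)
#   P26     nose tip                         (68: 31)
#   P27     right nostril corner             (68: 36)
#   P28-P39 outer lip contour                (68: 49-60)
#           P28 left corner, P31 top-mid, P34 right corner, P37 bottom-mid
#   P40-P47 inner lip contour                (68: 61-68)
#   P48-P50 nose bridge top->low             (68: 28-30)
MAP_68_TO_51 <- c(
  18:22,        # P0-P4
  23:27,        # P5-P9
  37:42,        # P10-P15
  43:48,        # P16-P21
  34L, 32L, 33L, 35L, 31L, 36L,  # P22-P27
  49:60,        # P28-P39
  61:68,        # P40-P47
  28:30         # P48-P50
)

AUX_MAP <- c(chin = 9L, left_face_side = 1L, right_face_side = 17L)

# Left/right partner of each primary index under reflection about the facial
# midline (0-based, position i+1 holds the mirror of Pi).  Used by the
# generator and by mirror-symmetry tests.
MIRROR_MAP <- {
  m <- integer(51)
  pairs <- rbind(
    c(0, 9), c(1, 8), c(2, 7), c(3, 6), c(4, 5),
    c(10, 19), c(11, 18), c(12, 17), c(13, 16), c(14, 21), c(15, 20),
    c(23, 27), c(24, 25),
    c(28, 34), c(29, 33), c(30, 32), c(35, 39), c(36, 38),
    c(40, 44), c(41, 43), c(45, 47)
  )
  selfs <- c(22, 26, 31, 37, 42, 46, 48, 49, 50)
  m[pairs[, 1] + 1L] <- pairs[, 2]
  m[pairs[, 2] + 1L] <- pairs[, 1]
  m[selfs + 1L] <- selfs
  m
}

#' The 68-to-51 landmark index map
#'
#' Returns the fixed reindexing used by [select_51()]: entry `i + 1` gives the
#' 1-based index into the 68-point layout of reorganized point `Pi`.
#'
#' @return Integer vector of length 51 plus an `aux` attribute naming the
#'   three jaw points retained as auxiliary boundary references.
#' @export
landmark_index_map <- function() {
  structure(MAP_68_TO_51, aux = AUX_MAP)
}

#' Construct a raw 68-point landmark set
#'
#' @param points Numeric 68 x 2 matrix of (x, y) pixel coordinates, origin
#'   top-left, y increasing downward.
#' @return An object of class `raw_landmarks68`.
#' @export
raw_landmarks68 <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 68L)
    stop_invalid("raw landmark set must have exactly 68 points, got %d", nrow(points))
  assert_finite_matrix(points, "raw landmarks")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points), class = "raw_landmarks68")
}

#' Construct a 51-point landmark set
#'
#' @param points Numeric 51 x 2 matrix, rows ordered P0..P50.
#' @param aux Numeric 3 x 2 matrix with rownames `chin`, `left_face_side`,
#'   `right_face_side`, same coordinate frame as `points`.
#' @param source Optional source identifier.
#' @param tilt_corrected Logical; whether the outer eye corners have been
#'   horizontally aligned.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, aux, source = NA_character_, tilt_corrected = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) != 51L)
    stop_invalid("landmark set must have exactly 51 points, got %d", nrow(points))
  assert_finite_matrix(points, "landmarks")
  aux <- as.matrix(aux)
  need <- c("chin", "left_face_side", "right_face_side")
  if (is.null(rownames(aux)) || !all(need %in% rownames(aux)))
    stop_invalid("aux must carry rows chin, left_face_side, right_face_side")
  aux <- aux[need, , drop = FALSE]
  assert_finite_matrix(aux, "auxiliary points")
  dimnames(points) <- list(paste0("P", 0:50), c("x", "y"))
  colnames(aux) <- c("x", "y")
  structure(
    list(points = points, aux = aux,
         meta = list(source = source, tilt_corrected = isTRUE(tilt_corrected))),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> 51 points, tilt_corrected=%s, source=%s\n",
              x$meta$tilt_corrected, x$meta$source))
  invisible(x)
}

# Accessor: point Pi (0-based index), as length-2 numeric.
pt <- function(lm, i) lm$points[i + 1L, ]

#' Select the 51 points of interest from a 68-point prediction
#'
#' Drops the 17 jaw-contour points and reorganizes the remainder into the
#' documented P0..P50 order; the chin and the two outermost jaw points are
#' retained as named auxiliary boundary references.
#'
#' @param raw A [raw_landmarks68()] object (or a bare 68 x 2 matrix).
#' @param source Optional source identifier propagated to the result.
#' @return A [landmark_set()].
#' @export
select_51 <- function(raw, source = NA_character_) {
  if (is.matrix(raw)) raw <- raw_landmarks68(raw)
  if (!inherits(raw, "raw_landmarks68"))
    stop_invalid("select_51() expects a raw_landmarks68 object or a 68 x 2 matrix")
  p <- raw$points
  aux <- p[AUX_MAP, , drop = FALSE]
  rownames(aux) <- names(AUX_MAP)
  landmark_set(p[MAP_68_TO_51, , drop = FALSE], aux, source = source)
}

#' Construct a similarity transform
#'
#' A 2 x 3 matrix whose linear block is `s * R` for a scale `s > 0` and a
#' proper rotation `R`; applied to homogeneous coordinates `(x, y, 1)`.
#'
#' @param matrix Numeric 2 x 3 matrix.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (!identical(dim(m), c(2L, 3L)) || !all(is.finite(m)))
    stop_invalid("similarity transform must be a finite 2 x 3 matrix")
  a <- m[, 1]; b <- m[, 2]
  if (abs(sum(a * b)) > 1e-8 * max(sum(a * a), 1) ||
      abs(sum(a * a) - sum(b * b)) > 1e-8 * max(sum(a * a), 1))
    stop_invalid("linear block is not a scaled rotation (columns not orthonormal up to scale)")
  if (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1] <= 0)
    stop_invalid("linear block must have positive determinant")
  structure(list(matrix = m), class = "similarity_transform")
}

# Rotation by `theta` radians about `center`, as a 2 x 3 similarity matrix.
# Under the y-down image convention a positive theta appears clockwise.
rotation_about <- function(theta, center) {
  co <- cos(theta); si <- sin(theta)
  R <- matrix(c(co, si, -si, co), 2, 2)
  t <- as.numeric(center) - R %*% as.numeric(center)
  similarity_transform(cbind(R, t))
}

#' Compute the tilt-correction transform
#'
#' Builds the similarity transform that rotates the face so the outer eye
#' corners (P10 and P19) become horizontally aligned.  The rotation is taken
#' about their midpoint, so the corner midpoint and the inter-corner distance
#' are preserved: a pure rotation, scale exactly 1.
#'
#' @param lm A [landmark_set()].
#' @return A [similarity_transform()].
#' @export
compute_tilt_transform <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  p10 <- pt(lm, 10); p19 <- pt(lm, 19)
  d <- p19 - p10
  if (sqrt(sum(d^2)) < .Machine$double.eps * 100)
    stop_degenerate("outer eye corners coincide; tilt angle undefined")
  theta <- atan2(d[2], d[1])   # rotate by -theta to zero the corner-line slope
  rotation_about(-theta, (p10 + p19) / 2)
}

#' Apply a similarity transform to a landmark set
#'
#' Maps every primary and auxiliary point through
#' `(x', y')^T = Tf %*% (x, y, 1)^T`.  The `tilt_corrected` flag of the result
#' is set from the post-transform geometry: it is `TRUE` when the outer eye
#' corners end up horizontally aligned within `1e-6` of the inter-corner
#' distance.
#'
#' @param lm A [landmark_set()].
#' @param tf A [similarity_transform()].
#' @return A transformed [landmark_set()].
#' @export
apply_transform <- function(lm, tf) {
  stopifnot(inherits(lm, "landmark_set"), inherits(tf, "similarity_transform"))
  m <- tf$matrix
  map <- function(p) sweep(p %*% t(m[, 1:2]), 2, m[, 3], "+")
  out <- landmark_set(map(lm$points),
                      {a <- map(lm$aux); rownames(a) <- rownames(lm$aux); a},
                      source = lm$meta$source)
  p10 <- pt(out, 10); p19 <- pt(out, 19)
  iod <- sqrt(sum((p19 - p10)^2))
  out$meta$tilt_corrected <- abs(p19[2] - p10[2]) <= 1e-6 * iod
  out
}

#' Tilt-correct a landmark set
#'
#' Convenience wrapper: [compute_tilt_transform()] followed by
#' [apply_transform()].  Idempotent up to floating tolerance.
#'
#' @param lm A [landmark_set()].
#' @return A tilt-corrected [landmark_set()].
#' @export
tilt_correct <- function(lm) apply_transform(lm, compute_tilt_transform(lm))

#' Rotate a landmark set in the image plane
#'
#' Rigid rotation of all primary and auxiliary points about `center`, used to
#' create augmented copies.  The result is never flagged `tilt_corrected`
#' (unless the rotation happens to leave the eye corners aligned, the flag is
#' recomputed from geometry and will be `FALSE` for any non-trivial angle).
#'
#' @param lm A [landmark_set()].
#' @param angle_deg Rotation angle in degrees; under the y-down convention a
#'   positive angle appears clockwise on screen.
#' @param center Length-2 rotation center; default is the midpoint of the
#'   outer eye corners.
#' @return A rotated [landmark_set()].
#' @export
rotate_landmarks <- function(lm, angle_deg, center = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  if (is.null(center)) center <- (pt(lm, 10) + pt(lm, 19)) / 2
  apply_transform(lm, rotation_about(angle_deg * pi / 180, center))
}
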