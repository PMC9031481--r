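# The 30 geometric measures: 28 distances plus two averaged heights.
#
# Endpoint ledger.  The distances are defined pictorially in the source
# material; this table fixes one endpoint choice per measure, consistent with
# every printed description.  All quantities are in pixels of the (tilt
# corrected) landmark frame.
#
#  A   head width                 d(left_face_side, right_face_side)
#  Bl  left eye width             d(P10, P13)        outer to inner corner
#  Br  right eye width            d(P16, P19)
#  C   mouth-to-chin              d(P37, chin)       bottom-mid outer lip
#  D   left eye to head side      d(P10, left_face_side)
#  E   right eye to head side     d(P19, right_face_side)
#  F   left eye to mouth          d(P10, P28)        outer corner to corner
#  G   right eye to mouth         d(P19, P34)
#  H   left eye to nose           d(P13, P22)        inner corner to nose base
#  I   right eye to nose          d(P16, P22)
#  J   nose to mouth, left        d(P23, P28)        nostril to mouth corner
#  K   nose to mouth, right       d(P27, P34)
#  L   left eyebrow mean height   mean over P0..P4 of the elevation above
#                                 the outer-eye-corner line [average value]
#  M   right eyebrow mean height  mean over P5..P9 of the same elevation
#      ("height" is face-intrinsic: y_eyeline - y_point in the y-down image
#       frame, so a raised brow has a larger height and the ratio L/M is
#       invariant to where the face sits in the image)
#  Nl  left eye opening, outer lid pair   d(P11, P15)
#  Nr  left eye opening, inner lid pair   d(P12, P14)
#  Ol  right eye opening, inner lid pair  d(P17, P21)
#  Or  right eye opening, outer lid pair  d(P18, P20)
#      (N-measures belong to the LEFT eye, O-measures to the RIGHT; the
#       second subscript is the lid pair's horizontal position in the image,
#       l = toward image left, r = toward image right.  Hence
#       N = (Nl + Nr)/2 is the left eye's mean opening, O the right eye's,
#       and the mirror pairs are Nl <-> Or (outer openings) and Nr <-> Ol
#       (inner openings), matching the outer-, inner- and average-opening
#       ratio features.)
#  Pl  mouth outer opening, left  d(P30, P38)        outer lip, left of midline
#  Pu  mouth inner opening, left  d(P41, P47)
#  Ql  mouth outer opening, right d(P32, P36)
#  Qu  mouth inner opening, right d(P43, P45)
#  R   left outer brow to mouth   d(P0, P28)
#  S   right outer brow to mouth  d(P9, P34)
#  T   left inner brow to mouth   d(P4, P28)
#  U   right inner brow to mouth  d(P5, P34)
#  Vl  left mouth half width      d(P28, mouth midline point)
#  Vr  right mouth half width     d(P34, mouth midline point)
#  W   mouth width                d(P28, P34)
#  X   nose base to mouth         d(P22, P31)        to top-mid outer lip
#
# The mouth midline point for Vl/Vr is the midpoint of the top-mid and
# bottom-mid outer-lip points (P31, P37), so the half widths respond to a
# corner pulled sideways OR up/down on one side only.
#
# Derived quantities (not counted among the 30, used only inside features):
#  N = (Nl + Nr) / 2, O = (Ol + Or) / 2   mean outer / inner eye openings
#  Wl = perimeter(P28, P29, P30, P31, P37, P38, P39)  left half-mouth
#  Wr = perimeter(P31, P32, P33, P34, P35, P36, P37)  right half-mouth

MEASURE_NAMES <- c(
  "A", "Bl", "Br", "C", "D", "E", "F", "G", "H", "I", "J", "K",
  "L", "M", "Nl", "Nr", "Ol", "Or", "Pl", "Pu", "Ql", "Qu",
  "R", "S", "T", "U", "Vl", "Vr", "W", "X"
)

#' Names of the 30 geometric measures
#'
#' @return Character vector of length 30 (28 distances plus the two averaged
#'   eyebrow heights `L` and `M`).
#' @export
measure_names <- function() MEASURE_NAMES

#' Compute the 30 geometric measures of a face
#'
#' Evaluates the documented endpoint ledger on a tilt-corrected landmark set:
#' 28 Euclidean distances plus the two mean eyebrow heights.  The returned
#' vector additionally carries a `derived` attribute with the quantities
#' `N`, `O` (mean outer/inner eye openings) and `Wl`, `Wr` (closed half-mouth
#' perimeters) consumed by the feature layer.
#'
#' @param lm A [landmark_set()]; a warning is raised if it is not flagged
#'   tilt-corrected.
#' @return Object of class `measure_set`: a named numeric vector of length 30,
#'   all entries finite and non-negative.
#' @export
compute_measures <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!isTRUE(lm$meta$tilt_corrected))
    warning("landmark set is not tilt-corrected; measures assume aligned eye corners",
            call. = FALSE)
  P <- function(i) lm$points[i + 1L, ]
  ax <- lm$aux

  mouth_mid <- (P(31) + P(37)) / 2

  m <- c(
    A  = euclidean(ax["left_face_side", ], ax["right_face_side", ]),
    Bl = euclidean(P(10), P(13)),
    Br = euclidean(P(16), P(19)),
    C  = euclidean(P(37), ax["chin", ]),
    D  = euclidean(P(10), ax["left_face_side", ]),
    E  = euclidean(P(19), ax["right_face_side", ]),
    F  = euclidean(P(10), P(28)),
    G  = euclidean(P(19), P(34)),
    H  = euclidean(P(13), P(22)),
    I  = euclidean(P(16), P(22)),
    J  = euclidean(P(23), P(28)),
    K  = euclidean(P(27), P(34)),
    L  = mean((P(10)[2] + P(19)[2]) / 2 - lm$points[1:5, "y"]),
    M  = mean((P(10)[2] + P(19)[2]) / 2 - lm$points[6:10, "y"]),
    Nl = euclidean(P(11), P(15)),
    Nr = euclidean(P(12), P(14)),
    Ol = euclidean(P(17), P(21)),
    Or = euclidean(P(18), P(20)),
    Pl = euclidean(P(30), P(38)),
    Pu = euclidean(P(41), P(47)),
    Ql = euclidean(P(32), P(36)),
    Qu = euclidean(P(43), P(45)),
    R  = euclidean(P(0), P(28)),
    S  = euclidean(P(9), P(34)),
    T  = euclidean(P(4), P(28)),
    U  = euclidean(P(5), P(34)),
    Vl = euclidean(P(28), mouth_mid),
    Vr = euclidean(P(34), mouth_mid),
    W  = euclidean(P(28), P(34)),
    X  = euclidean(P(22), P(31))
  )
  if (m[["W"]] <= 0 || m[["A"]] <= 0)
    stop_degenerate("degenerate face: zero mouth width or zero head width")
  if (!all(is.finite(m)))
    stop_degenerate("non-finite measure encountered")

  derived <- c(
    N  = (m[["Nl"]] + m[["Nr"]]) / 2,
    O  = (m[["Ol"]] + m[["Or"]]) / 2,
    Wl = closed_perimeter(lm$points[c(28, 29, 30, 31, 37, 38, 39) + 1L, ]),
    Wr = closed_perimeter(lm$points[c(31, 32, 33, 34, 35, 36, 37) + 1L, ])
  )
  structure(m, derived = derived, class = c("measure_set", "numeric"))
}

#' @export
print.measure_set <- function(x, ...) {
  cat("<measure_set> 30 measures (pixels; L, M are mean eyebrow heights)\n")
  print(setNames(round(as.numeric(x), 3), names(x)))
  invisible(x)
}
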