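# The 29-element asymmetry feature vector f0..f28.
#
# Feature roster (angles in degrees via angle_between, ratios dimensionless,
# slopes dimensionless):
#   f0  |angle(P0,  P9)|   eyebrows, outer points
#   f1  |angle(P2,  P7)|   eyebrows, mid points
#   f2  |angle(P4,  P5)|   eyebrows, inner points
#   f3  max(L/M, M/L)      mean eyebrow height ratio
#   f4  m(P0,  P9)         eyebrow outer slope
#   f5  m(P2,  P7)         eyebrow mid slope
#   f6  m(P4,  P5)         eyebrow inner slope
#   f7  |angle(P10, P19)|  outer eye corners
#   f8  max(Bl/Br, Br/Bl)  eye width ratio
#   f9  max(D/E,  E/D)     eye-to-head-side ratio
#   f10 max(H/I,  I/H)     eye-to-nose ratio
#   f11 max(N/O,  O/N)     average opening ratio: left eye N=(Nl+Nr)/2 vs
#                          right eye O=(Ol+Or)/2
#   f12 max(Nl/Or, Or/Nl)  eyes' outer opening ratio
#   f13 max(Nr/Ol, Ol/Nr)  eyes' inner opening ratio
#   f14 |angle(P28, P34)|  mouth corners
#   f15 max(F/G,  G/F)     eye-to-mouth ratio
#   f16 max(Pl/Ql, Ql/Pl)  mouth outer opening ratio
#   f17 max(Pu/Qu, Qu/Pu)  mouth inner opening ratio
#   f18 max(Vl/A, Vr/A)    larger mouth half-width over head width
#   f19 max(Pl/W, Ql/W)    larger outer opening over mouth width
#   f20 max(Pu/W, Qu/W)    larger inner opening over mouth width
#   f21 max(Wl/W, Wr/W)    larger half-mouth perimeter over mouth width
#   f22 |angle(P23, P27)|  nostril corners
#   f23 |angle(P22, P37)|  nose base vs bottom-mid lip
#   f24 max(J/K,  K/J)     nose-to-mouth ratio
#   f25 max(T/A,  U/A)     inner-brow-to-mouth over head width
#   f26 max(R/A,  S/A)     outer-brow-to-mouth over head width
#   f27 C/A                mouth-to-chin over head width
#   f28 X/A                nose-to-mouth over head width
#
# Degenerate eye openings (a fully closed synthetic eye has zero lid
# separation) would make the opening ratios infinite; openings entering a
# ratio denominator are floored at a small fraction of the inter-ocular
# distance, mimicking the ~1 px floor a real lid landmark pair keeps.

OPENING_FLOOR_IOD <- 1e-3

#' Compute the 29 asymmetry features
#'
#' Evaluates the documented feature roster (angle, slope, ratio features) on
#' the measures of a tilt-corrected landmark set.  All features are built
#' from angles, slopes or ratios of distances and are therefore invariant to
#' translation and uniform scaling of the input; after tilt correction they
#' are also invariant to in-plane rotation.
#'
#' @param lm A [landmark_set()], ideally tilt-corrected.
#' @param convention Angle convention passed to [angle_between()].
#' @return Named numeric vector `f0` .. `f28` of class `feature_vector`.
#' @export
compute_features <- function(lm, convention = "atan2_xy") {
  ms <- compute_measures(lm)
  dv <- attr(ms, "derived")
  m <- as.list(ms)
  P <- function(i) lm$points[i + 1L, ]
  ang <- function(i, j) abs(angle_between(P(i), P(j), convention = convention))

  iod <- euclidean(P(10), P(19))
  floor_v <- OPENING_FLOOR_IOD * iod
  op <- function(v) max(v, floor_v)
  Nl <- op(m$Nl); Nr <- op(m$Nr); Ol <- op(m$Ol); Or <- op(m$Or)
  N <- op(dv[["N"]]); O <- op(dv[["O"]])
  Pl <- op(m$Pl); Ql <- op(m$Ql); Pu <- op(m$Pu); Qu <- op(m$Qu)

  f <- c(
    ang(0, 9), ang(2, 7), ang(4, 5),
    ratio_max(m$L, m$M),
    slope_between(P(0), P(9)), slope_between(P(2), P(7)), slope_between(P(4), P(5)),
    ang(10, 19),
    ratio_max(m$Bl, m$Br),
    ratio_max(m$D, m$E),
    ratio_max(m$H, m$I),
    ratio_max(N, O),
    ratio_max(Nl, Or),
    ratio_max(Nr, Ol),
    ang(28, 34),
    ratio_max(m$F, m$G),
    ratio_max(Pl, Ql),
    ratio_max(Pu, Qu),
    max(m$Vl / m$A, m$Vr / m$A),
    max(Pl / m$W, Ql / m$W),
    max(Pu / m$W, Qu / m$W),
    max(dv[["Wl"]] / m$W, dv[["Wr"]] / m$W),
    ang(23, 27),
    ang(22, 37),
    ratio_max(m$J, m$K),
    max(m$T / m$A, m$U / m$A),
    max(m$R / m$A, m$S / m$A),
    m$C / m$A,
    m$X / m$A
  )
  names(f) <- feature_names()
  if (!all(is.finite(f)))
    stop_degenerate("non-finite feature encountered")
  structure(f, class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 29 features\n")
  print(setNames(round(as.numeric(x), 4), names(x)))
  invisible(x)
}

#' Extract a feature table from a gesture dataset
#'
#' Tilt-corrects every landmark set in the dataset and computes its feature
#' vector, binding the dataset's label/grade/subject/provenance metadata.
#'
#' @param ds A [gesture_dataset()].
#' @return A `data.frame` with columns `f0` .. `f28`, `label` (integer 0-5),
#'   `grade`, `subject`, `origin_id`, `provenance`.
#' @export
extract_features <- function(ds) {
  stopifnot(inherits(ds, "gesture_dataset"))
  feats <- t(vapply(ds$landmarks,
                    function(lm) as.numeric(compute_features(tilt_correct(lm))),
                    numeric(29)))
  colnames(feats) <- feature_names()
  cbind(as.data.frame(feats), ds$info)
}
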