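# Parametric synthetic landmark generator.
#
# Emulates the six posed gestures on a canonical symmetric face so the whole
# pipeline is testable without access-restricted patient imagery.  Palsy is
# modeled as one-sided attenuation of the gesture displacement field: points
# on the affected half move by (1 - severity) of their healthy displacement,
# midline points by (1 - severity / 2).  Coordinates are in pixels with an
# inter-ocular (outer corner to outer corner) distance of 100.

#' Canonical symmetric face template
#'
#' A rest-pose 51-point face, bilaterally symmetric about the vertical
#' midline, with the three auxiliary boundary points.  Inter-ocular distance
#' (P10 to P19) is 100 pixels and serves as the scale unit for gesture
#' displacement magnitudes.
#'
#' @return An object of class `face_template`: a list with `points` (51 x 2),
#'   `aux` (3 x 2) and `iod`.
#' @export
face_template <- function() {
  pts <- matrix(NA_real_, 51, 2)
  set <- function(i, x, y) pts[i + 1L, ] <<- c(x, y)
  # eyebrows
  set(0, -55, -25); set(1, -45, -30); set(2, -35, -32); set(3, -25, -30); set(4, -15, -26)
  set(5,  15, -26); set(6,  25, -30); set(7,  35, -32); set(8,  45, -30); set(9,  55, -25)
  # eyes (opening 12)
  set(10, -50, 0); set(11, -40, -6); set(12, -28, -6)
  set(13, -20, 0); set(14, -28,  6); set(15, -40,  6)
  set(16,  20, 0); set(17,  28, -6); set(18,  40, -6)
  set(19,  50, 0); set(20,  40,  6); set(21,  28,  6)
  # nose
  set(22, 0, 42); set(23, -12, 40); set(24, -6, 42); set(25, 6, 42)
  set(26, 0, 35); set(27, 12, 40)
  # outer lip (width 60)
  set(28, -30, 70); set(29, -20, 64); set(30, -10, 61); set(31, 0, 60)
  set(32,  10, 61); set(33,  20, 64); set(34, 30, 70)
  set(35,  20, 76); set(36,  10, 79); set(37, 0, 80); set(38, -10, 79); set(39, -20, 76)
  # inner lip
  set(40, -24, 70); set(41, -10, 66); set(42, 0, 65); set(43, 10, 66)
  set(44,  24, 70); set(45,  10, 74); set(46, 0, 75); set(47, -10, 74)
  # nose bridge
  set(48, 0, 5); set(49, 0, 15); set(50, 0, 25)
  aux <- rbind(chin = c(0, 115), left_face_side = c(-75, 10), right_face_side = c(75, 10))
  # shift into positive image coordinates (origin top-left, y down); the
  # facial midline sits at x = 120, the eye line at y = 80
  offset <- c(120, 80)
  pts <- sweep(pts, 2, offset, "+")
  aux <- sweep(aux, 2, offset, "+")
  colnames(aux) <- colnames(pts) <- c("x", "y")
  structure(list(points = pts, aux = aux, iod = 100, midline_x = offset[1]),
            class = "face_template")
}

# Displacement fields, one per movement kind, at unit amplitude.  Returned as
# list(points = 51 x 2, aux = 3 x 2) in template pixels (inter-ocular
# distance 100).  y is image-down, so raising an element means negative dy.
gesture_field <- function(kind) {
  d <- matrix(0, 51, 2)
  da <- matrix(0, 3, 2, dimnames = list(c("chin", "left_face_side", "right_face_side"), NULL))
  add <- function(i, dx, dy) d[i + 1L, ] <<- d[i + 1L, ] + c(dx, dy)
  switch(kind,
    rest = NULL,
    brow_raise = {
      # inner + outer brow raisers; lids open wider with the movement
      up <- c(9, 11, 12, 11, 10)
      for (k in 0:4) add(k, 0, -up[k + 1])
      for (k in 5:9) add(k, 0, -up[10 - k])
      for (k in c(11, 12, 17, 18)) add(k, 0, -3)
      for (k in c(14, 15, 20, 21)) add(k, 0, 3)
    },
    eye_closure = {
      # lids converge onto the corner line (opening 12 -> 2 at unit amplitude)
      for (k in c(11, 12, 17, 18)) add(k, 0, 5)
      for (k in c(14, 15, 20, 21)) add(k, 0, -5)
      # slight brow drop accompanies a full-effort closure
      for (k in 0:9) add(k, 0, 2)
    },
    smile_open = {
      # lip corner puller + lips part + jaw drop
      add(28, -10, -8); add(34, 10, -8)
      add(29, -6, -5); add(33, 6, -5)
      add(40, -7, -5); add(44, 7, -5)
      for (k in c(35, 39)) add(k, 0, 4)
      for (k in c(36, 38)) add(k, 0, 7)
      add(37, 0, 8)
      for (k in c(45, 47)) add(k, 0, 6)
      add(46, 0, 7)
      for (k in c(41, 43)) add(k, 0, -2)
      add(42, 0, -2)
      # eyes narrow slightly when smiling
      for (k in c(11, 12, 17, 18)) add(k, 0, 1.5)
      da["chin", 2] <- 6
    },
    smile_closed = {
      # lip corner puller + lip stretcher; lips stay together
      add(28, -12, -5); add(34, 12, -5)
      for (k in c(29, 39)) add(k, -8, -3)
      for (k in c(33, 35)) add(k, 8, -3)
      for (k in c(30, 38)) add(k, -4, -1)
      for (k in c(32, 36)) add(k, 4, -1)
      add(40, -10, -4); add(44, 10, -4)
      for (k in c(41, 47)) add(k, -5, -1)
      for (k in c(43, 45)) add(k, 5, -1)
      # thinner lips under stretch
      for (k in c(30, 31, 32)) add(k, 0, 1)
      for (k in c(36, 37, 38)) add(k, 0, -1)
      for (k in c(11, 12, 17, 18)) add(k, 0, 1)
    },
    pucker = {
      # lip puckerer: mouth narrows toward the midline, slight protrusion
      for (k in 28:47) {
        d[k + 1L, 1] <- d[k + 1L, 1] - 0.45 * face_template_x(k)
      }
      for (k in c(30, 31, 32, 41, 42, 43)) add(k, 0, -2)
      for (k in c(36, 37, 38, 45, 46, 47)) add(k, 0, 2)
    },
    lip_depression = {
      # lower-lip depressor showing the lower teeth; close to an open smile
      add(28, -6, 2); add(34, 6, 2)
      for (k in c(35, 39)) add(k, 0, 7)
      for (k in c(36, 38)) add(k, 0, 10)
      add(37, 0, 11)
      for (k in c(45, 47)) add(k, 0, 9)
      add(46, 0, 10)
      da["chin", 2] <- 7
    },
    stop_invalid("unknown gesture field '%s'", kind)
  )
  list(points = d, aux = da)
}

# Midline-centered template x coordinate of point Pk (memoized).
face_template_x <- local({
  tx <- NULL
  function(k) {
    if (is.null(tx)) {
      tpl <- face_template()
      tx <<- tpl$points[, 1] - tpl$midline_x
    }
    tx[k + 1L]
  }
})

GESTURE_KINDS <- c("rest", "brow_raise", "eye_closure", "smile_open",
                   "smile_closed", "pucker")

# Resting droop of a paralyzed hemiface: brow ptosis, upper-lid sag and a
# fallen mouth corner.  Defined symmetrically for both halves; at generation
# time it is scaled by severity on the affected side only, so it is present
# in EVERY gesture of an affected subject, including rest.
droop_field <- function() {
  d <- matrix(0, 51, 2)
  add <- function(i, dx, dy) d[i + 1L, ] <<- c(dx, dy)
  for (k in 0:4) add(k, 0, 3); for (k in 5:9) add(k, 0, 3)
  for (k in c(11, 12, 17, 18)) add(k, 0, 2)    # upper lid sags
  for (k in c(14, 15, 20, 21)) add(k, 0, 1)    # lower lid sags less: eye narrows
  add(28, 2, 5); add(34, -2, 5)                # mouth corner falls inward/down
  for (k in c(29, 39)) add(k, 1, 3); for (k in c(33, 35)) add(k, -1, 3)
  for (k in c(30, 38)) add(k, 0, 1.5); for (k in c(32, 36)) add(k, 0, 1.5)
  add(40, 2, 4); add(44, -2, 4)
  for (k in c(41, 47)) add(k, 0, 1.5); for (k in c(43, 45)) add(k, 0, 1.5)
  add(23, 0, 1); add(27, 0, 1)
  d
}

# Weight of the droop field per point: severity on the affected half,
# severity / 2 on the midline, 0 on the healthy half.
droop_weights <- function(xs, severity, affected_side) {
  side_sign <- if (affected_side == "left") -1 else 1
  w <- numeric(length(xs))
  w[sign(xs) == side_sign] <- severity
  w[xs == 0] <- severity / 2
  w
}

# Per-point attenuation weights for one-sided palsy.
palsy_weights <- function(xs, severity, affected_side) {
  side_sign <- if (affected_side == "left") -1 else 1
  w <- rep(1, length(xs))
  affected <- sign(xs) == side_sign
  midline <- xs == 0
  w[affected] <- 1 - severity
  w[midline] <- 1 - severity / 2
  w
}

#' Generate one synthetic landmark set
#'
#' Applies a gesture displacement field to the symmetric template, attenuates
#' it on the affected side according to palsy severity, adds the severity-
#' scaled resting droop of the affected hemiface (present in every gesture,
#' including rest), Gaussian coordinate noise and a global in-plane head
#' tilt.
#'
#' @param tpl A [face_template()].
#' @param gesture Integer class code 0-5 (rest, eyebrow elevation, eye
#'   closure, wide-open smile, closed-mouth smile, pucker).
#' @param severity Palsy severity in `[0, 1]`; 0 is healthy.  Displacements on
#'   the affected side are scaled by `1 - severity`, midline points by
#'   `1 - severity / 2`.
#' @param affected_side `"left"` or `"right"` (image convention).
#' @param amplitude Gesture effort multiplier (1 = full effort).
#' @param noise_sd Landmark jitter standard deviation in pixels (the template
#'   inter-ocular distance is 100 px).
#' @param global_tilt Head tilt in degrees applied after the gesture.
#' @param seed Optional integer; when supplied the RNG state is seeded so the
#'   face is reproducible in isolation.  When `NULL` the current RNG stream
#'   is used (the dataset generator seeds once).
#' @param kind Internal override naming a displacement field directly (e.g.
#'   `"lip_depression"`, which has no class code of its own).
#' @return A [landmark_set()] (not tilt-corrected).
#' @export
generate_face <- function(tpl = face_template(), gesture = 0L, severity = 0,
                          affected_side = c("left", "right"), amplitude = 1,
                          noise_sd = 0, global_tilt = 0, seed = NULL,
                          kind = NULL) {
  affected_side <- match.arg(affected_side)
  if (is.null(kind)) {
    if (length(gesture) != 1L || is.na(gesture) || !(gesture %in% 0:5))
      stop_invalid("gesture must be an integer class code in 0..5")
    kind <- GESTURE_KINDS[gesture + 1L]
  }
  if (severity < 0 || severity > 1) stop_invalid("severity must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  fld <- gesture_field(kind)
  xc <- tpl$points[, 1] - tpl$midline_x   # midline-centered x for sidedness
  xca <- tpl$aux[, 1] - tpl$midline_x
  w <- palsy_weights(xc, severity, affected_side)
  wa <- palsy_weights(xca, severity, affected_side)
  wd <- droop_weights(xc, severity, affected_side)
  pts <- tpl$points + amplitude * fld$points * w + droop_field() * wd
  aux <- tpl$aux + amplitude * fld$aux * wa
  if (noise_sd > 0) {
    pts <- pts + matrix(rnorm(102, sd = noise_sd), 51, 2)
    aux <- aux + matrix(rnorm(6, sd = noise_sd), 3, 2)
  }
  rownames(aux) <- rownames(tpl$aux)
  lm <- landmark_set(pts, aux)
  if (global_tilt != 0) lm <- rotate_landmarks(lm, global_tilt)
  lm
}

# The eight posed movements and their class grouping:
# rest -> 0, eyebrow elevation -> 1, light + full eye closure -> 2,
# full smile and lip depression -> 3, light smile -> 3 or 4 depending on how
# far the lips part, pucker -> 5.
MOVEMENT_ROSTER <- data.frame(
  movement = 1:8,
  kind = c("rest", "brow_raise", "eye_closure", "eye_closure",
           "light_smile", "smile_open", "pucker", "lip_depression"),
  label = c(0L, 1L, 2L, 2L, NA_integer_, 3L, 5L, 3L),
  amp_lo = c(1.0, 0.8, 0.40, 0.90, NA, 0.90, 0.8, 0.8),
  amp_hi = c(1.0, 1.2, 0.60, 1.10, NA, 1.20, 1.2, 1.1),
  stringsAsFactors = FALSE
)

#' Construct a gesture dataset
#'
#' A labeled collection of landmark sets with subject, grade and provenance
#' metadata.
#'
#' @param landmarks List of [landmark_set()] objects.
#' @param info `data.frame` with one row per landmark set and columns
#'   `label` (integer 0-5), `grade`, `subject`, `origin_id`, `provenance`
#'   (`"original"` or `"rotated"`), `angle` (augmentation angle, 0 for
#'   originals).
#' @return Object of class `gesture_dataset`.
#' @export
gesture_dataset <- function(landmarks, info) {
  if (!is.list(landmarks) || !all(vapply(landmarks, inherits, TRUE, "landmark_set")))
    stop_invalid("landmarks must be a list of landmark_set objects")
  need <- c("label", "grade", "subject", "origin_id", "provenance", "angle")
  if (!is.data.frame(info) || nrow(info) != length(landmarks) ||
      !all(need %in% names(info)))
    stop_invalid("info must have one row per landmark set and columns %s",
                 paste(need, collapse = ", "))
  if (!all(info$label %in% 0:5)) stop_invalid("labels must be class codes 0..5")
  rownames(info) <- NULL
  structure(list(landmarks = landmarks, info = info), class = "gesture_dataset")
}

#' @export
length.gesture_dataset <- function(x) length(x$landmarks)

#' @export
print.gesture_dataset <- function(x, ...) {
  cat(sprintf("<gesture_dataset> %d samples, %d subjects\n",
              length(x), length(unique(x$info$subject))))
  print(table(label = x$info$label))
  invisible(x)
}

#' Subset a gesture dataset
#'
#' @param x A [gesture_dataset()].
#' @param i Index vector over samples.
#' @param ... Unused.
#' @return A [gesture_dataset()] restricted to `i`.
#' @export
`[.gesture_dataset` <- function(x, i, ...) {
  gesture_dataset(x$landmarks[i], x$info[i, , drop = FALSE])
}

#' Generate a synthetic gesture dataset
#'
#' Simulates `n_subjects` subjects each performing the eight posed movements
#' (rest, eyebrow elevation, light and full eye closure, light and full
#' smile, pucker, lip depression), grouped into the six gesture classes.
#' Light smiles are assigned to class 3 (wide-open) or class 4 (closed-mouth)
#' depending on whether the drawn lip-parting fraction exceeds
#' `light_smile_open_threshold`.  Each subject receives a palsy grade (cycled
#' through `grades`), a severity drawn uniformly from that grade's band, and
#' a random affected side; every sample gets an independent head tilt.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param grades Character vector of grade names to cycle over subjects;
#'   default all six bands.
#' @param movements Number of movements per subject (first `movements` of the
#'   roster; default all 8).
#' @param noise_sd Landmark jitter SD in pixels (inter-ocular distance 100).
#' @param tilt_range Head tilts drawn uniformly from `[-tilt_range, tilt_range]`
#'   degrees.
#' @param light_smile_open_threshold Lip-parting fraction above which a light
#'   smile counts as wide-open (class 3) rather than closed-mouth (class 4).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A [gesture_dataset()].
#' @export
generate_dataset <- function(n_subjects, grades = palsy_grades(), movements = 8,
                             noise_sd = 0.5, tilt_range = 10,
                             light_smile_open_threshold = 0.5, seed = 1L) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  if (movements < 1 || movements > 8) stop_invalid("movements must be in 1..8")
  bands <- list(
    normal = c(0, 0.05), `near-normal` = c(0.05, 0.2), mild = c(0.2, 0.4),
    moderate = c(0.4, 0.6), severe = c(0.6, 0.85), complete = c(0.85, 1)
  )
  if (!all(grades %in% names(bands)))
    stop_invalid("unknown grade; expected one of %s", paste(names(bands), collapse = ", "))
  set.seed(seed)
  tpl <- face_template()
  roster <- MOVEMENT_ROSTER[seq_len(movements), ]
  landmarks <- vector("list", n_subjects * movements)
  info <- vector("list", n_subjects * movements)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    grade <- grades[(s - 1L) %% length(grades) + 1L]
    band <- bands[[grade]]
    severity <- runif(1, band[1], band[2])
    side <- sample(c("left", "right"), 1)
    subject <- sprintf("S%03d", s)
    for (r in seq_len(nrow(roster))) {
      idx <- idx + 1L
      mv <- roster[r, ]
      tilt <- runif(1, -tilt_range, tilt_range)
      if (mv$kind == "light_smile") {
        # closed-mouth smile base plus a drawn amount of lip parting
        part <- runif(1)
        lm0 <- generate_face(tpl, kind = "smile_closed", severity = severity,
                             affected_side = side, amplitude = runif(1, 0.5, 0.8),
                             noise_sd = 0, global_tilt = 0)
        open_fld <- gesture_field("smile_open")
        w <- palsy_weights(tpl$points[, 1] - tpl$midline_x, severity, side)
        part_d <- open_fld$points
        part_d[, 1] <- 0                       # parting is vertical only
        pts <- lm0$points + 0.8 * part * part_d * w
        if (noise_sd > 0) pts <- pts + matrix(rnorm(102, sd = noise_sd), 51, 2)
        lm <- landmark_set(pts, lm0$aux + matrix(rnorm(6, sd = noise_sd), 3, 2,
                                                 dimnames = dimnames(lm0$aux)))
        if (tilt != 0) lm <- rotate_landmarks(lm, tilt)
        label <- if (part > light_smile_open_threshold) 3L else 4L
      } else {
        amp <- runif(1, mv$amp_lo, mv$amp_hi)
        lm <- generate_face(tpl, kind = mv$kind, severity = severity,
                            affected_side = side, amplitude = amp,
                            noise_sd = noise_sd, global_tilt = tilt)
        label <- mv$label
      }
      landmarks[[idx]] <- lm
      info[[idx]] <- data.frame(
        label = label, grade = grade, subject = subject,
        origin_id = sprintf("%s_m%d", subject, mv$movement),
        provenance = "original", angle = 0,
        severity = severity, affected_side = side,
        stringsAsFactors = FALSE
      )
    }
  }
  gesture_dataset(landmarks, do.call(rbind, info))
}
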