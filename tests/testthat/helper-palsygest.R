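# Shared fixtures and independent oracles.

# A tilt-corrected rest-pose template face.
template_face <- function() tilt_correct(generate_face(face_template(), 0L))

# Random valid landmark set: template plus bounded jitter (keeps the face
# non-degenerate), optionally posed and tilted.
random_face <- function(jitter = 1.5, gesture = 0L, severity = 0, tilt = 0) {
  generate_face(face_template(), gesture, severity = severity,
                noise_sd = jitter, global_tilt = tilt)
}

# A synthetic 68-point prediction laid out in the standard order, built by
# inverting the package's selection map so jaw points get plausible values.
raw68_fixture <- function() {
  tpl <- face_template()
  p68 <- matrix(NA_real_, 68, 2)
  p68[landmark_index_map(), ] <- tpl$points
  # jaw contour: ellipse through the auxiliary side points and the chin
  t <- seq(0, pi, length.out = 17)
  p68[1:17, ] <- cbind(tpl$midline_x - 75 * cos(t), 90 + 105 * sin(t))
  p68[c(1, 9, 17), ] <- tpl$aux[c("left_face_side", "chin", "right_face_side"), ]
  raw_landmarks68(p68)
}

# Independent naive transcription of the 29 features, written directly from
# the feature roster with its own endpoint bookkeeping; deliberately scalar
# and loop-based, sharing no code with compute_features().
naive_features <- function(lm) {
  p <- lm$points  # 51 x 2, row i = P(i-1)
  ax <- lm$aux
  P <- function(i) p[i + 1, ]
  ang <- function(a, b) {
    dx <- a[1] - b[1]; dy <- a[2] - b[2]
    if (dx == 0 && dy == 0) return(0)
    abs(atan2(dx, dy) * 180 / pi)
  }
  slp <- function(a, b) {
    dy <- a[2] - b[2]; dx <- a[1] - b[1]
    if (dx == 0) { if (dy == 0) 0 else sign(dy) * 1e6 } else dy / dx
  }
  dst <- function(a, b) sqrt(sum((a - b)^2))
  per <- function(idx) {
    s <- 0
    for (i in seq_along(idx)) {
      j <- if (i == length(idx)) 1 else i + 1
      s <- s + dst(P(idx[i]), P(idx[j]))
    }
    s
  }
  iod <- dst(P(10), P(19))
  flo <- function(v) max(v, 1e-3 * iod)

  A <- dst(ax["left_face_side", ], ax["right_face_side", ])
  Bl <- dst(P(10), P(13)); Br <- dst(P(16), P(19))
  C <- dst(P(37), ax["chin", ])
  D <- dst(P(10), ax["left_face_side", ]); E <- dst(P(19), ax["right_face_side", ])
  Ff <- dst(P(10), P(28)); G <- dst(P(19), P(34))
  H <- dst(P(13), P(22)); I <- dst(P(16), P(22))
  J <- dst(P(23), P(28)); K <- dst(P(27), P(34))
  eye_y <- (P(10)[2] + P(19)[2]) / 2
  L <- mean(eye_y - c(P(0)[2], P(1)[2], P(2)[2], P(3)[2], P(4)[2]))
  M <- mean(eye_y - c(P(5)[2], P(6)[2], P(7)[2], P(8)[2], P(9)[2]))
  Nl <- flo(dst(P(11), P(15))); Nr <- flo(dst(P(12), P(14)))
  Ol <- flo(dst(P(17), P(21))); Or <- flo(dst(P(18), P(20)))
  Nn <- flo((Nl + Nr) / 2); Oo <- flo((Ol + Or) / 2)
  Pl <- flo(dst(P(30), P(38))); Pu <- flo(dst(P(41), P(47)))
  Ql <- flo(dst(P(32), P(36))); Qu <- flo(dst(P(43), P(45)))
  R <- dst(P(0), P(28)); S <- dst(P(9), P(34))
  Tt <- dst(P(4), P(28)); U <- dst(P(5), P(34))
  mid <- (P(31) + P(37)) / 2
  Vl <- dst(P(28), mid); Vr <- dst(P(34), mid)
  W <- dst(P(28), P(34))
  Wl <- per(c(28, 29, 30, 31, 37, 38, 39)); Wr <- per(c(31, 32, 33, 34, 35, 36, 37))
  X <- dst(P(22), P(31))
  mr <- function(a, b) max(a / b, b / a)

  unname(c(ang(P(0), P(9)), ang(P(2), P(7)), ang(P(4), P(5)),
    mr(L, M),
    slp(P(0), P(9)), slp(P(2), P(7)), slp(P(4), P(5)),
    ang(P(10), P(19)),
    mr(Bl, Br), mr(D, E), mr(H, I),
    mr(Nn, Oo), mr(Nl, Or), mr(Nr, Ol),
    ang(P(28), P(34)),
    mr(Ff, G), mr(Pl, Ql), mr(Pu, Qu),
    max(Vl / A, Vr / A), max(Pl / W, Ql / W), max(Pu / W, Qu / W),
    max(Wl / W, Wr / W),
    ang(P(23), P(27)), ang(P(22), P(37)),
    mr(J, K), max(Tt / A, U / A), max(R / A, S / A),
    C / A, X / A))
}

# Reflect a landmark set about the vertical line through the eye-corner
# midpoint, relabeling left/right indices so the result is again a valid
# face.
mirror_face <- function(lm) {
  mm <- palsygest:::MIRROR_MAP
  cx <- (lm$points[11, 1] + lm$points[20, 1]) / 2
  pts <- lm$points[mm + 1L, , drop = FALSE]
  pts[, 1] <- 2 * cx - pts[, 1]
  aux <- lm$aux[c("chin", "right_face_side", "left_face_side"), ]
  rownames(aux) <- c("chin", "left_face_side", "right_face_side")
  aux[, 1] <- 2 * cx - aux[, 1]
  landmark_set(pts, aux, tilt_corrected = lm$meta$tilt_corrected)
}

# Tiny linearly separable two-class feature table for classifier tests.
toy_separable <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  x <- matrix(runif(2 * n_per_class * 29, 0, 0.2), ncol = 29)
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + 2
  y <- rep(c(0L, 1L), each = n_per_class)
  list(x = x, y = y)
}

# Small clean dataset reused across evaluation tests.
small_dataset <- function(n_subjects = 12, seed = 11, noise_sd = 0.3) {
  generate_dataset(n_subjects, noise_sd = noise_sd, seed = seed)
}
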