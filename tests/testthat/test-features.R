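test_that("measure set has the 30 documented entries with valid values", {
  m <- compute_measures(template_face())
  expect_s3_class(m, "measure_set")
  expect_length(m, 30L)
  expect_named(m, measure_names())
  expect_true(all(is.finite(m)) && all(m >= 0))
  expect_gt(m[["W"]], 0); expect_gt(m[["A"]], 0)
  dv <- attr(m, "derived")
  expect_named(dv, c("N", "O", "Wl", "Wr"))
  # half-mouth perimeter exceeds half the mouth chord
  expect_gte(dv[["Wl"]], m[["W"]] / 2)
  expect_gte(dv[["Wr"]], m[["W"]] / 2)
})

test_that("measures respect template symmetry and scale homogeneity", {
  lm <- template_face()
  m <- compute_measures(lm)
  expect_equal(m[["Bl"]], m[["Br"]])
  expect_equal(m[["D"]], m[["E"]])
  expect_equal(m[["H"]], m[["I"]])
  expect_equal(m[["Nl"]], m[["Or"]])   # mirror pairs: outer openings
  expect_equal(m[["Nr"]], m[["Ol"]])   # inner openings
  expect_equal(m[["Vl"]], m[["Vr"]])
  # uniform x2 scaling doubles every measure (distances and mean heights)
  lm2 <- lm
  lm2$points <- lm$points * 2
  lm2$aux <- lm$aux * 2
  m2 <- compute_measures(lm2)
  expect_equal(as.numeric(m2), 2 * as.numeric(m), tolerance = 1e-12)
})

test_that("Wl matches a hand-applied perimeter on the documented point list", {
  lm <- random_face(jitter = 2)
  lm <- tilt_correct(lm)
  idx <- c(28, 29, 30, 31, 37, 38, 39) + 1L
  pts <- lm$points[idx, ]
  manual <- 0
  for (j in 1:6) manual <- manual + euclidean(pts[j, ], pts[j + 1, ])
  manual <- manual + euclidean(pts[1, ], pts[7, ])
  expect_equal(attr(compute_measures(lm), "derived")[["Wl"]], manual,
               tolerance = 1e-12)
})

test_that("degenerate faces raise degenerate-geometry errors", {
  lm <- template_face()
  lm$points[, ] <- 1  # all points coincide: zero mouth and head width
  lm$aux[, ] <- 1
  expect_error(compute_measures(lm), class = "palsygest_degenerate_geometry")
})

test_that("feature vector has 29 finite entries with documented conventions", {
  f <- compute_features(template_face())
  expect_s3_class(f, "feature_vector")
  expect_length(f, 29L)
  expect_named(f, paste0("f", 0:28))
  expect_true(all(is.finite(f)))
  # symmetric rest face: reciprocal max-ratios 1, horizontal-pair angles 90,
  # slopes 0
  recip <- paste0("f", c(3, 8, 9, 10, 11, 12, 13, 15, 16, 17, 24))
  expect_equal(unname(f[recip]), rep(1, length(recip)), tolerance = 1e-12)
  expect_equal(unname(f[c("f0", "f1", "f2", "f7", "f14", "f22")]),
               rep(90, 6), tolerance = 1e-12)
  expect_equal(unname(f[c("f4", "f5", "f6")]), rep(0, 3), tolerance = 1e-12)
  expect_gt(f[["f27"]], 0); expect_gt(f[["f28"]], 0)
})

test_that("features match an independent naive transcription on random faces", {
  set.seed(101)
  for (i in 1:100) {
    lm <- tilt_correct(random_face(jitter = runif(1, 0.2, 3),
                                   gesture = sample(0:5, 1),
                                   severity = runif(1)))
    f <- compute_features(lm)
    expect_equal(as.numeric(f), naive_features(lm), tolerance = 1e-9)
  }
})

test_that("features are invariant to translation, scale and input rotation", {
  set.seed(7)
  for (i in 1:10) {
    lm <- random_face(jitter = 1.5, gesture = sample(0:5, 1))
    f0 <- compute_features(tilt_correct(lm))
    shifted <- lm
    shifted$points <- sweep(lm$points, 2, c(137.3, -42.9), "+")
    shifted$aux <- sweep(lm$aux, 2, c(137.3, -42.9), "+")
    scaled <- lm
    scaled$points <- lm$points * 3.7
    scaled$aux <- lm$aux * 3.7
    rotated <- rotate_landmarks(lm, runif(1, -30, 30))
    expect_equal(as.numeric(compute_features(tilt_correct(shifted))),
                 as.numeric(f0), tolerance = 1e-9)
    expect_equal(as.numeric(compute_features(tilt_correct(scaled))),
                 as.numeric(f0), tolerance = 1e-9)
    expect_equal(as.numeric(compute_features(tilt_correct(rotated))),
                 as.numeric(f0), tolerance = 1e-6)
  }
})

test_that("mirror reflection preserves ratio features and angle deviations", {
  set.seed(19)
  ratio_like <- paste0("f", c(3, 8:13, 15:21, 24:28))
  swapped_angles <- c("f0", "f1", "f2", "f7", "f14", "f22")
  for (g in 0:5) {
    lm <- tilt_correct(random_face(jitter = 1, gesture = g, severity = 0.6))
    f <- compute_features(lm)
    fm <- compute_features(mirror_face(lm))
    expect_equal(as.numeric(fm[ratio_like]), as.numeric(f[ratio_like]),
                 tolerance = 1e-9)
    # a left/right endpoint swap maps |angle| = 90 + d to 90 - d: the
    # deviation from horizontal is what reflection preserves
    expect_equal(abs(as.numeric(fm[swapped_angles]) - 90),
                 abs(as.numeric(f[swapped_angles]) - 90), tolerance = 1e-9)
    # the midline pair f23 reflects onto itself
    expect_equal(fm[["f23"]], f[["f23"]], tolerance = 1e-9)
    # slopes flip sign
    expect_equal(as.numeric(fm[c("f4", "f5", "f6")]),
                 -as.numeric(f[c("f4", "f5", "f6")]), tolerance = 1e-9)
  }
})

test_that("ratio floor: max-ratio features are >= 1, equal 1 only when balanced", {
  set.seed(23)
  recip <- paste0("f", c(3, 8, 9, 10, 11, 12, 13, 15, 16, 17, 24))
  for (i in 1:20) {
    lm <- tilt_correct(random_face(jitter = 2, gesture = sample(0:5, 1),
                                   severity = runif(1)))
    f <- compute_features(lm)
    expect_true(all(f[recip] >= 1))
  }
  # strict inequality under one-sided attenuation
  lm <- tilt_correct(generate_face(face_template(), 2, severity = 0.8))
  f <- compute_features(lm)
  expect_gt(f[["f11"]], 1)
  expect_gt(f[["f12"]], 1)
})

test_that("one-sided eye closure raises the opening asymmetry features", {
  open_f <- compute_features(template_face())
  closed <- tilt_correct(generate_face(face_template(), 2, severity = 1,
                                       affected_side = "left"))
  closed_f <- compute_features(closed)
  for (nm in c("f11", "f12", "f13"))
    expect_gt(closed_f[[nm]], open_f[[nm]])
  # affected-side (left) eye opening stays at that subject's rest-pose value
  rest_same_subject <- tilt_correct(generate_face(face_template(), 0,
                                                  severity = 1,
                                                  affected_side = "left"))
  m <- compute_measures(closed)
  m0 <- compute_measures(rest_same_subject)
  expect_equal(m[["Nl"]], m0[["Nl"]], tolerance = 1e-9)
  expect_lt(m[["Or"]], m0[["Or"]])
})
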