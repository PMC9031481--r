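test_that("select_51 drops the 17 jaw points and keeps the index semantics", {
  raw <- raw68_fixture()
  lm <- select_51(raw)
  expect_s3_class(lm, "landmark_set")
  expect_equal(nrow(lm$points), 51L)            # 68 - 17 jaw points
  expect_equal(nrow(lm$aux), 3L)
  # mapping table is a bijection into the non-jaw range
  map <- landmark_index_map()
  expect_length(map, 51L)
  expect_setequal(map, 18:68)
  # index-semantics constraints of the documented reindexing
  tpl <- face_template()
  expect_equal(unname(lm$points["P10", ]), unname(tpl$points[11, ]))  # left outer eye
  expect_equal(unname(lm$points["P19", ]), unname(tpl$points[20, ]))  # right outer eye
  # symmetric template: P10/P19 mirror about the midline x = 120, brows too
  cx <- 2 * tpl$midline_x
  expect_equal(lm$points["P10", "x"], cx - lm$points["P19", "x"])
  expect_equal(lm$points["P0", "x"], cx - lm$points["P9", "x"])
  expect_equal(lm$points["P28", "x"], cx - lm$points["P34", "x"])
  # auxiliaries captured from the dropped contour
  expect_equal(unname(lm$aux["chin", ]), unname(tpl$aux["chin", ]))
})

test_that("select_51 rejects wrong-sized input", {
  expect_error(raw_landmarks68(matrix(0, 51, 2)), class = "palsygest_invalid_input")
  expect_error(select_51(matrix(0, 51, 2)), class = "palsygest_invalid_input")
  bad <- matrix(0, 68, 2); bad[5, 1] <- NaN
  expect_error(raw_landmarks68(bad), class = "palsygest_invalid_input")
})

test_that("tilt transform aligns the outer eye corners", {
  lm <- random_face(jitter = 0, tilt = 11.3)
  tf <- compute_tilt_transform(lm)
  # pure rotation: scale of the linear block is 1
  expect_equal(sqrt(sum(tf$matrix[, 1]^2)), 1, tolerance = 1e-12)
  out <- apply_transform(lm, tf)
  p10 <- out$points["P10", ]; p19 <- out$points["P19", ]
  iod <- sqrt(sum((p19 - p10)^2))
  expect_lt(abs(p19["y"] - p10["y"]), 1e-6 * iod)
  expect_true(out$meta$tilt_corrected)
  # midpoint and inter-corner distance preserved
  expect_equal((p10 + p19) / 2,
               (lm$points["P10", ] + lm$points["P19", ]) / 2, tolerance = 1e-9)
  expect_equal(iod, sqrt(sum((lm$points["P19", ] - lm$points["P10", ])^2)),
               tolerance = 1e-9)
})

test_that("tilt transform matches the closed-form rotation oracle", {
  # two-point oracle: corners (100,120) and (200,140); angle -atan2(20,100)
  lm <- face_template()
  shift <- c(100, 120) - lm$points[11, ]
  pts <- sweep(lm$points, 2, shift, "+")
  pts[20, ] <- c(200, 140)
  aux <- sweep(lm$aux, 2, shift, "+")
  lm2 <- landmark_set(pts, aux)
  tf <- compute_tilt_transform(lm2)
  theta <- -atan2(20, 100)
  expect_equal(tf$matrix[1, 1], cos(theta), tolerance = 1e-12)
  expect_equal(tf$matrix[2, 1], sin(theta), tolerance = 1e-12)
  out <- apply_transform(lm2, tf)
  expect_equal(unname(out$points["P10", "y"]), unname(out$points["P19", "y"]),
               tolerance = 1e-9)
})

test_that("already-horizontal corners give the identity rotation", {
  lm <- template_face()
  tf <- compute_tilt_transform(lm)
  expect_equal(tf$matrix[, 1:2], diag(2), tolerance = 1e-12)
})

test_that("coincident eye corners raise a degenerate-geometry error", {
  lm <- template_face()
  lm$points[20, ] <- lm$points[11, ]
  expect_error(compute_tilt_transform(lm), class = "palsygest_degenerate_geometry")
})

test_that("apply_transform implements the homogeneous matrix product", {
  lm <- template_face()
  # identity
  id <- similarity_transform(cbind(diag(2), c(0, 0)))
  expect_equal(apply_transform(lm, id)$points, lm$points)
  # pure translation by (5, -3)
  tr <- similarity_transform(cbind(diag(2), c(5, -3)))
  expect_equal(apply_transform(lm, tr)$points,
               sweep(lm$points, 2, c(5, -3), "+"))
  expect_equal(apply_transform(lm, tr)$aux["chin", ],
               lm$aux["chin", ] + c(5, -3))
  # 90-degree rotation about the origin maps (1, 0) to (0, 1):
  # [x'; y'] = [[c, -s], [s, c]] %*% [x; y] with c=0, s=1
  rot <- similarity_transform(cbind(matrix(c(0, 1, -1, 0), 2, 2), c(0, 0)))
  p <- lm$points
  out <- apply_transform(lm, rot)$points
  expect_equal(unname(out[1, ]), c(-p[1, 2], p[1, 1]))
})

test_that("similarity_transform validates its linear block", {
  expect_error(similarity_transform(cbind(matrix(c(1, 0, 0, 2), 2), c(0, 0))),
               class = "palsygest_invalid_input")       # unequal scales
  expect_error(similarity_transform(cbind(matrix(c(0, 1, 1, 0), 2), c(0, 0))),
               class = "palsygest_invalid_input")       # reflection
})

test_that("rotate_landmarks is rigid and invertible", {
  lm <- random_face(jitter = 1)
  expect_equal(rotate_landmarks(lm, 0)$points, lm$points)
  back <- rotate_landmarks(rotate_landmarks(lm, 23), -23)
  expect_equal(back$points, lm$points, tolerance = 1e-9)
  expect_false(rotate_landmarks(lm, 10)$meta$tilt_corrected)
})

test_that("tilt correction is idempotent and rotation-invariant up to translation", {
  for (theta in c(-30, -12, 0.5, 7, 30)) {
    lm <- random_face(jitter = 1)
    c1 <- tilt_correct(lm)
    c2 <- tilt_correct(c1)
    expect_equal(c2$points, c1$points, tolerance = 1e-9)
    cr <- tilt_correct(rotate_landmarks(lm, theta, center = c(13, -40)))
    # same shape up to global translation: pairwise vectors agree
    ref <- sweep(c1$points, 2, c1$points[1, ])
    got <- sweep(cr$points, 2, cr$points[1, ])
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("landmark JSON and CSV round-trip", {
  lm <- random_face(jitter = 2)
  jf <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lm, jf, meta = list(label = 3L, subject = "S9"))
  got <- read_landmarks_json(jf)
  expect_equal(got$landmarks$points, lm$points)
  expect_equal(got$landmarks$aux, lm$aux)
  expect_equal(got$meta$label, 3L)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(lm, cf)
  expect_equal(read_landmarks_csv(cf)$points, lm$points, tolerance = 1e-12)
  expect_error(read_landmarks_json(cf), class = "palsygest_format_error")
})
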