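test_that("augmentation count law holds and metadata is preserved", {
  ds <- small_dataset(4)                 # 32 samples
  for (m in list(numeric(0), 5, c(5, 10), c(5, 10, 15))) {
    aug <- augment_with_rotations(ds, m)
    expect_length(aug, (2 * length(m) + 1) * length(ds))
  }
  aug <- augment_with_rotations(ds, c(5, 10, 15))
  expect_equal(sum(aug$info$provenance == "original"), length(ds))
  rot <- aug$info[aug$info$provenance == "rotated", ]
  expect_setequal(unique(rot$angle), c(5, -5, 10, -10, 15, -15))
  # labels and grades preserved per origin
  first <- ds$info$origin_id[1]
  copies <- aug$info[aug$info$origin_id == first, ]
  expect_equal(nrow(copies), 7L)
  expect_length(unique(copies$label), 1L)
  expect_length(unique(copies$grade), 1L)
  expect_error(augment_with_rotations(ds, -5), class = "palsygest_invalid_input")
})

test_that("rotated copies reproduce the original features after tilt correction", {
  ds <- small_dataset(2, noise_sd = 0.2)
  aug <- augment_with_rotations(ds, c(5, 10, 15))
  ft <- extract_features(aug)
  fcols <- paste0("f", 0:28)
  for (oid in unique(ft$origin_id)) {
    block <- as.matrix(ft[ft$origin_id == oid, fcols])
    ref <- block[1, ]
    expect_lt(max(abs(sweep(block, 2, ref))), 1e-6)
  }
})

test_that("stratified grouped k-fold satisfies the partition laws", {
  ds <- small_dataset(10)
  aug <- augment_with_rotations(ds, c(5, 10, 15))
  labels <- aug$info$label
  groups <- aug$info$origin_id
  splits <- stratified_group_kfold(labels, groups, k = 5, seed = 2)
  tests <- lapply(splits, `[[`, "test")
  # disjoint and exhaustive
  expect_equal(sort(unlist(tests)), seq_along(labels))
  expect_equal(sum(lengths(tests)), length(labels))
  for (f in seq_along(splits))
    expect_length(intersect(splits[[f]]$train, splits[[f]]$test), 0L)
  # grouping: no origin id spans two folds
  fold_of_group <- lapply(tests, function(t) unique(groups[t]))
  expect_equal(sum(lengths(fold_of_group)), length(unique(groups)))
  # approximate stratification: each fold sees every class
  for (t in tests) expect_setequal(unique(labels[t]), 0:5)
})

test_that("ungrouped split ignores origin ids", {
  labels <- rep(0:1, each = 50)
  groups <- rep(1:10, 10)
  splits <- stratified_group_kfold(labels, groups, k = 5, seed = 1, group = FALSE)
  expect_equal(sort(unlist(lapply(splits, `[[`, "test"))), 1:100)
  sizes <- lengths(lapply(splits, `[[`, "test"))
  expect_true(all(sizes == 20))
})

test_that("rare classes trigger a stratification warning with fallback", {
  labels <- c(rep(0L, 20), rep(1L, 3))
  expect_warning(splits <- stratified_group_kfold(labels, k = 5, seed = 1),
                 "stratification")
  expect_equal(sort(unlist(lapply(splits, `[[`, "test"))), seq_along(labels))
})

test_that("classification metrics follow the printed formulas", {
  # diagonal matrix: perfect scores
  cm <- diag(c(10, 20, 30, 5, 5, 10))
  mets <- classification_metrics(cm)
  expect_equal(mets$accuracy, 1)
  expect_equal(mets$per_class$f1, rep(1, 6))
  # hand-built counts: class 0 with TP=8, FN=2, FP=4
  cm <- matrix(0, 6, 6)
  cm[1, 1] <- 8; cm[1, 2] <- 2; cm[2, 1] <- 4; cm[2, 2] <- 26
  mets <- classification_metrics(cm)
  expect_equal(mets$per_class$recall[1], 8 / 10)
  expect_equal(mets$per_class$precision[1], 8 / 12)
  expect_equal(mets$per_class$f1[1], 2 * 8 / (2 * 8 + 4 + 2))
  expect_equal(mets$accuracy, 34 / 40)
  # F1 equals the harmonic mean of precision and recall when both nonzero
  pc <- mets$per_class[1, ]
  expect_equal(pc$f1, 2 * pc$precision * pc$recall / (pc$precision + pc$recall))
  # zero-denominator convention: absent class reports 0 and is flagged
  expect_equal(mets$per_class$recall[3], 0)
  expect_true(mets$per_class$zero_denominator[3])
})

test_that("confusion counts tally actual x predicted", {
  cc <- confusion_counts(c(0, 0, 1, 2), c(0, 1, 1, 2))
  expect_equal(dim(cc), c(6L, 6L))
  expect_equal(sum(cc), 4L)
  expect_equal(cc[1, 1], 1L); expect_equal(cc[1, 2], 1L)
  expect_error(confusion_counts(0:2, 0:1), class = "palsygest_invalid_input")
})

test_that("cross-validation report is internally consistent", {
  ds <- small_dataset(10)
  ft <- extract_features(ds)
  rep <- run_cv_experiment(ft, mlp_hyperparams(H = 12, N = 150), k = 5, seed = 4)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$folds), 5L)
  expect_equal(rep$folds$correct + rep$folds$errors, rep$folds$n)
  expect_equal(sum(rep$folds$n), nrow(ft))
  # report accuracy equals recomputation from the pooled confusion matrix
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(sum(rep$folds$correct), sum(diag(rep$confusion)))
  expect_true(all(rep$per_class$recall >= 0 & rep$per_class$recall <= 1))
  # deterministic given seed
  rep2 <- run_cv_experiment(ft, mlp_hyperparams(H = 12, N = 150), k = 5, seed = 4)
  expect_identical(rep$confusion, rep2$confusion)
})

test_that("per-grade experiment mirrors the grade structure", {
  ds <- small_dataset(12)                # two subjects per grade
  ft <- extract_features(ds)
  reps <- suppressWarnings(
    run_per_grade_experiment(ft, mlp_hyperparams(H = 8, N = 100), k = 2, seed = 5)
  )
  expect_setequal(names(reps), palsy_grades())
  sizes <- vapply(reps, function(r) sum(r$confusion), numeric(1))
  expect_equal(sum(sizes), nrow(ft))
  for (r in reps) expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  # missing grade is skipped with a warning
  sub <- ft[ft$grade != "mild", ]
  w <- capture_warnings(
    run_per_grade_experiment(sub, mlp_hyperparams(H = 8, N = 50), k = 2, seed = 5)
  )
  expect_true(any(grepl("skipped", w)))
})
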