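# Experimental protocol: rotation augmentation, grouped stratified k-fold
# cross-validation, the four classification metrics, and per-grade reports.

#' Augment a dataset with rotated copies
#'
#' For every sample and every magnitude in `magnitudes`, adds two copies
#' rotated by the positive and the negative angle.  Output size is therefore
#' `(2 * length(magnitudes) + 1) * length(ds)`.  Labels, grades and subject
#' ids are preserved; copies carry provenance `"rotated"`, the signed angle,
#' and the `origin_id` of their source sample.  Because features are computed
#' after tilt correction, rotated copies yield (noise-free) feature vectors
#' equal to their original's: the augmentation validates rotation invariance
#' while exercising the alignment path.
#'
#' Default magnitudes are 5, 10, 15 degrees: three rotations in opposite
#' directions plus the original data, within the small head-tilt regime that
#' tilt correction targets.
#'
#' @param ds A [gesture_dataset()].
#' @param magnitudes Positive angles in degrees; an empty vector returns the
#'   input unchanged.
#' @return An augmented [gesture_dataset()].
#' @export
augment_with_rotations <- function(ds, magnitudes = c(5, 10, 15)) {
  stopifnot(inherits(ds, "gesture_dataset"))
  if (length(ds) == 0L) stop_invalid("cannot augment an empty dataset")
  if (length(magnitudes) == 0L) return(ds)
  if (any(magnitudes <= 0)) stop_invalid("rotation magnitudes must be positive")
  angles <- c(0, as.vector(rbind(magnitudes, -magnitudes)))
  n <- length(ds)
  landmarks <- vector("list", n * length(angles))
  info <- vector("list", length(angles))
  k <- 0L
  for (a in angles) {
    inf <- ds$info
    if (a == 0) {
      lms <- ds$landmarks
    } else {
      lms <- lapply(ds$landmarks, rotate_landmarks, angle_deg = a)
      inf$provenance <- "rotated"
      inf$angle <- a
    }
    landmarks[k * n + seq_len(n)] <- lms
    k <- k + 1L
    info[[k]] <- inf
  }
  gesture_dataset(landmarks, do.call(rbind, info))
}

#' Grouped stratified k-fold split
#'
#' Partitions sample indices into `k` cross-validation folds, approximately
#' stratified by class.  With `group = TRUE` (default) all samples sharing a
#' `groups` value (e.g. all rotated copies of one original photograph) are
#' kept in the same fold, preventing train/test leakage of augmented copies;
#' `group = FALSE` splits plain sample-wise.
#'
#' @param labels Integer class labels, one per sample.
#' @param groups Group ids, one per sample (ignored when `group = FALSE`).
#' @param k Number of folds, >= 2.
#' @param seed Integer seed for the shuffle.
#' @param group Whether to respect group boundaries.
#' @return List of `k` elements, each `list(train =, test =)` index vectors;
#'   test sets are pairwise disjoint and exhaustive.
#' @export
stratified_group_kfold <- function(labels, groups = seq_along(labels), k = 5,
                                   seed = 1L, group = TRUE) {
  n <- length(labels)
  if (k < 2) stop_invalid("k must be >= 2")
  if (!group) groups <- seq_len(n)
  if (length(groups) != n) stop_invalid("labels and groups lengths differ")
  set.seed(seed)
  gid <- as.character(groups)
  ug <- unique(gid)
  # one label per group (majority in the rare mixed case)
  glab <- vapply(ug, function(g) {
    tab <- table(labels[gid == g])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  fold_of <- setNames(integer(length(ug)), ug)
  offset <- 0L
  for (cl in sort(unique(glab))) {
    gs <- ug[glab == cl]
    if (length(gs) < k)
      warning(sprintf("class %d has only %d group(s) for %d folds; stratification is approximate",
                      cl, length(gs), k), call. = FALSE)
    gs <- sample(gs)
    # deal round-robin, rotating the starting fold between classes so small
    # classes do not pile onto fold 1
    fold_of[gs] <- ((seq_along(gs) - 1L + offset) %% k) + 1L
    offset <- (offset + length(gs)) %% k
  }
  lapply(seq_len(k), function(f) {
    test <- unname(which(fold_of[gid] == f))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Confusion counts
#'
#' Tallies a 6 x 6 confusion matrix (rows = actual, columns = predicted).
#'
#' @param actual,predicted Integer class codes 0-5.
#' @param n_classes Number of classes (default 6).
#' @return Integer matrix of class `confusion_counts`.
#' @export
confusion_counts <- function(actual, predicted, n_classes = 6L) {
  if (length(actual) != length(predicted))
    stop_invalid("actual and predicted lengths differ")
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(actual, levels = lv), factor(predicted, levels = lv))
  structure(matrix(as.integer(cm), n_classes, n_classes,
                   dimnames = list(actual = lv, predicted = lv)),
            class = c("confusion_counts", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy (trace over total) and, per class one-vs-rest,
#' recall `TP / (TP + FN)`, precision `TP / (TP + FP)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`.  A metric with a zero denominator is
#' reported as 0 and flagged in the `zero_denominator` column.
#'
#' @param cm A square count matrix (rows = actual, columns = predicted).
#' @return List with `accuracy`, `per_class` (`data.frame` with columns
#'   `class`, `recall`, `precision`, `f1`, `zero_denominator`) and
#'   `confusion`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    stop_invalid("confusion matrix must be square with non-negative counts")
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- data.frame(
    class = 0:(nrow(cm) - 1L),
    recall = safe(tp, tp + fn),
    precision = safe(tp, tp + fp),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    zero_denominator = (tp + fn) == 0 | (tp + fp) == 0,
    row.names = NULL
  )
  list(accuracy = if (total > 0) sum(tp) / total else 0,
       per_class = per_class, confusion = cm)
}

new_eval_report <- function(folds, confusion, extra = list()) {
  mets <- classification_metrics(confusion)
  structure(c(list(folds = folds,
                   accuracy = mets$accuracy,
                   per_class = mets$per_class,
                   confusion = confusion),
              extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall accuracy %.2f%% over %d samples\n",
              100 * x$accuracy, sum(x$confusion)))
  print(x$folds, row.names = FALSE)
  cat("per class:\n")
  print(transform(x$per_class, recall = round(recall, 4),
                  precision = round(precision, 4), f1 = round(f1, 4)),
        row.names = FALSE)
  invisible(x)
}

# Resolve a dataset argument into a feature table.
as_feature_table <- function(data) {
  if (inherits(data, "gesture_dataset")) extract_features(data)
  else if (is.data.frame(data)) data
  else stop_invalid("expected a gesture_dataset or a feature table data.frame")
}

#' Run a k-fold cross-validation experiment
#'
#' Splits the data with [stratified_group_kfold()], trains one MLP per fold
#' on the remaining folds and evaluates on the held-out fold, pooling the
#' per-fold confusion counts.  Deterministic given `seed` and `hp`.
#'
#' @param data A [gesture_dataset()] (features are extracted after tilt
#'   correction) or a feature table `data.frame` with columns `f0`..`f28`,
#'   `label` and optionally `origin_id`.
#' @param hp [mlp_hyperparams()].
#' @param k Number of folds.
#' @param seed Seed for the fold split.
#' @param group Keep augmented copies of one original in the same fold
#'   (requires an `origin_id` column; set `FALSE` for a plain split).
#' @return An `eval_report`: per-fold counts, overall accuracy, per-class
#'   metrics, pooled confusion matrix.
#' @export
run_cv_experiment <- function(data, hp = mlp_hyperparams(), k = 5, seed = 1L,
                              group = TRUE) {
  ft <- as_feature_table(data)
  groups <- if (group && !is.null(ft$origin_id)) ft$origin_id else seq_len(nrow(ft))
  splits <- stratified_group_kfold(as.integer(ft$label), groups, k = k,
                                   seed = seed, group = group)
  cm <- matrix(0L, 6, 6, dimnames = list(actual = 0:5, predicted = 0:5))
  folds <- data.frame(fold = seq_len(k), n = 0L, correct = 0L, errors = 0L,
                      accuracy = NA_real_)
  for (f in seq_len(k)) {
    tr <- ft[splits[[f]]$train, , drop = FALSE]
    te <- ft[splits[[f]]$test, , drop = FALSE]
    model <- train_mlp(tr, hp)
    pred <- predict(model, te)$label
    cm_f <- confusion_counts(as.integer(te$label), pred)
    cm <- cm + cm_f
    folds$n[f] <- nrow(te)
    folds$correct[f] <- sum(diag(cm_f))
    folds$errors[f] <- nrow(te) - folds$correct[f]
    folds$accuracy[f] <- folds$correct[f] / nrow(te)
  }
  new_eval_report(folds, cm, extra = list(hp = hp, seed = seed, grouped = group))
}

#' Run one cross-validation experiment per palsy grade
#'
#' Restricts the dataset to each grade in turn and runs an independent
#' [run_cv_experiment()] with the same hyperparameters, mirroring a
#' per-severity evaluation.  Grades absent from the data are skipped with a
#' warning.
#'
#' @inheritParams run_cv_experiment
#' @param grades Grades to evaluate; defaults to the six standard bands.
#' @return Named list of `eval_report` objects, one per grade present.
#' @export
run_per_grade_experiment <- function(data, hp = mlp_hyperparams(), k = 5,
                                     seed = 1L, group = TRUE,
                                     grades = palsy_grades()) {
  ft <- as_feature_table(data)
  if (is.null(ft$grade)) stop_invalid("dataset carries no grade labels")
  out <- list()
  for (g in grades) {
    sub <- ft[ft$grade == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("grade '%s' absent from dataset; skipped", g), call. = FALSE)
      next
    }
    out[[g]] <- run_cv_experiment(sub, hp, k = k, seed = seed, group = group)
  }
  out
}
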