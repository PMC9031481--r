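# Six-class gesture classifier: single-hidden-layer backpropagation MLP.

#' MLP hyperparameters
#'
#' Container for the five training hyperparameters of the gesture MLP.
#' Defaults are the optimized values used for the palsy gesture task:
#' learning rate `L = 0.2045`, momentum `M = 0.1909`, `H = 95` hidden units,
#' seed `S = 0`, `N = 5000` training epochs.  Note `L` and `M` here are
#' hyperparameters, unrelated to the eyebrow-height measures of the same
#' name, which live in the measure namespace.
#'
#' @param L Learning rate in `(0, 1]`.
#' @param M Momentum in `[0, 1)`.
#' @param H Number of hidden units (one hidden layer), >= 1.
#' @param S Integer seed for weight initialization and epoch shuffling.
#' @param N Number of training epochs, >= 1.
#' @return Object of class `mlp_hyperparams`.
#' @export
mlp_hyperparams <- function(L = 0.2045, M = 0.1909, H = 95L, S = 0L, N = 5000L) {
  if (!(L > 0 && L <= 1)) stop_invalid("learning rate L must be in (0, 1]")
  if (!(M >= 0 && M < 1)) stop_invalid("momentum M must be in [0, 1)")
  if (H < 1) stop_invalid("H (hidden units) must be >= 1")
  if (N < 1) stop_invalid("N (epochs) must be >= 1")
  structure(list(L = L, M = M, H = as.integer(H), S = as.integer(S),
                 N = as.integer(N)), class = "mlp_hyperparams")
}

#' @export
print.mlp_hyperparams <- function(x, ...) {
  cat(sprintf("<mlp_hyperparams> L=%g M=%g H=%d S=%d N=%d\n",
              x$L, x$M, x$H, x$S, x$N))
  invisible(x)
}

# Coerce training input to list(x = numeric matrix, y = integer labels).
as_training_xy <- function(data) {
  if (is.data.frame(data)) {
    fn <- feature_names()
    if (!all(fn %in% names(data)) || !("label" %in% names(data)))
      stop_invalid("feature table must have columns f0..f28 and label")
    x <- as.matrix(data[, fn])
    y <- as.integer(data$label)
  } else if (is.list(data) && !is.null(data$x)) {
    x <- as.matrix(data$x); y <- as.integer(data$y)
  } else {
    stop_invalid("training data must be a feature table or list(x=, y=)")
  }
  if (nrow(x) == 0L) stop_invalid("empty training set")
  if (ncol(x) != 29L)
    stop_invalid("feature vectors must have length 29, got %d", ncol(x))
  if (!all(is.finite(x))) stop_invalid("non-finite feature values")
  if (anyNA(y) || !all(y %in% 0:5)) stop_invalid("labels must be class codes 0..5")
  list(x = x, y = y)
}

# Per-attribute min-max normalization to [-1, 1]; constant attributes map to 0.
fit_normalizer <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

apply_normalizer <- function(norm, x) {
  rng <- norm$max - norm$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2, norm$min), 2, rng, "/") * 2 - 1
  out[, norm$max == norm$min] <- 0
  out
}

#' Train the gesture MLP
#'
#' Trains one hidden layer of `H` sigmoid units and 6 sigmoid output units by
#' online backpropagation (squared error) with learning rate `L` and momentum
#' `M` for `N` epochs, examples reshuffled every epoch, all randomness driven
#' by seed `S`.  Feature attributes are min-max normalized to `[-1, 1]` using
#' statistics of the training set only; the fitted normalizer travels with
#' the model and is reused verbatim at prediction time.
#'
#' Training is deterministic: the same data (in the same order) and the same
#' hyperparameters produce bit-identical weights.
#'
#' @param train Feature table `data.frame` (columns `f0`..`f28`, `label`) or
#'   `list(x = matrix, y = labels)`.
#' @param hp An [mlp_hyperparams()] object.
#' @return Object of class `gesture_model` with elements `W1`
#'   (`30 x H`, last row the hidden biases), `W2` (`(H+1) x 6`), `norm`,
#'   `classes`, `hp`.
#' @export
train_mlp <- function(train, hp = mlp_hyperparams()) {
  stopifnot(inherits(hp, "mlp_hyperparams"))
  d <- as_training_xy(train)
  if (length(unique(d$y)) < 2L)
    stop_invalid("training set must contain at least 2 classes")
  norm <- fit_normalizer(d$x)
  xn <- apply_normalizer(norm, d$x)
  w <- mlp_train_cpp(xn, d$y, 6L, hp$H, hp$L, hp$M, hp$N, hp$S)
  structure(list(W1 = w$W1, W2 = w$W2, norm = norm, classes = 0:5, hp = hp),
            class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf("<gesture_model> 29-%d-6 MLP (L=%g M=%g N=%d S=%d)\n",
              x$hp$H, x$hp$L, x$hp$M, x$hp$N, x$hp$S))
  invisible(x)
}

# Scores for a matrix of raw (unnormalized) feature rows.
model_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != 29L)
    stop_invalid("feature vectors must have length 29, got %d", ncol(x))
  if (!all(is.finite(x))) stop_invalid("non-finite feature values")
  s <- mlp_forward_cpp(apply_normalizer(model$norm, x), model$W1, model$W2)
  colnames(s) <- as.character(model$classes)
  s
}

#' Predict gesture classes
#'
#' Forward pass through a trained [train_mlp()] model.  The predicted label
#' is the argmax of the 6 output activations; ties break toward the lowest
#' class index.
#'
#' @param object A `gesture_model`.
#' @param newdata A single feature vector (length 29), a matrix of rows, or a
#'   feature table `data.frame`.
#' @param ... Unused.
#' @return For a single vector, `list(label =, scores =)`; otherwise
#'   `list(label = integer vector, scores = n x 6 matrix)`.
#' @export
predict.gesture_model <- function(object, newdata, ...) {
  single <- is.numeric(newdata) && is.null(dim(newdata))
  if (single) newdata <- matrix(as.numeric(newdata), nrow = 1)
  if (is.data.frame(newdata)) {
    fn <- feature_names()
    if (!all(fn %in% names(newdata)))
      stop_invalid("feature table must have columns f0..f28")
    newdata <- as.matrix(newdata[, fn])
  }
  s <- model_scores(object, newdata)
  lab <- object$classes[max.col(s, ties.method = "first")]
  if (single) list(label = lab[1], scores = s[1, ]) else list(label = lab, scores = s)
}

#' Save / load a gesture model
#'
#' Models are serialized as versioned JSON weight bundles; a load of a saved
#' model reproduces predictions bit-identically.
#'
#' @param model A `gesture_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `gesture_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gesture_model"))
  # doubles are serialized as %.17g strings: JSON numbers lose the last two
  # significant digits through jsonlite, and the round-trip must reproduce
  # predictions bit-identically
  hex <- function(m) {
    out <- sprintf("%.17g", m)
    dim(out) <- dim(m)
    out
  }
  payload <- list(
    format = "palsygest_mlp", version = 1L,
    hp = unclass(model$hp), classes = model$classes,
    norm = list(min = hex(model$norm$min), max = hex(model$norm$max)),
    W1 = hex(model$W1), W2 = hex(model$W2)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop_format("cannot parse model file: %s",
                                                      conditionMessage(e)))
  if (!identical(payload$format, "palsygest_mlp"))
    stop_format("not a palsygest model file")
  if (!identical(as.integer(payload$version), 1L))
    stop_format("unsupported model version %s", payload$version)
  hp <- do.call(mlp_hyperparams, as.list(payload$hp))
  unhex <- function(m) {
    out <- as.numeric(m)
    if (anyNA(out)) stop_format("non-numeric weight in model file")
    if (!is.null(dim(m))) dim(out) <- dim(m)
    out
  }
  W1 <- unhex(as.matrix(payload$W1)); W2 <- unhex(as.matrix(payload$W2))
  if (nrow(W1) != 30L || ncol(W2) != 6L || ncol(W1) + 1L != nrow(W2))
    stop_format("model weight shapes are inconsistent")
  structure(list(W1 = W1, W2 = W2,
                 norm = list(min = unhex(payload$norm$min),
                             max = unhex(payload$norm$max)),
                 classes = as.integer(payload$classes), hp = hp),
            class = "gesture_model")
}
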