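#' @keywords internal
"_PACKAGE"

#' @useDynLib palsygest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Classed conditions so callers (and tests) can distinguish failure modes.
pg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "palsygest_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_invalid <- function(msg, ...) pg_stop("palsygest_invalid_input", msg, ...)
stop_degenerate <- function(msg, ...) pg_stop("palsygest_degenerate_geometry", msg, ...)
stop_format <- function(msg, ...) pg_stop("palsygest_format_error", msg, ...)

assert_finite_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 2L)
    stop_invalid("%s must be a numeric matrix with 2 columns", what)
  if (!all(is.finite(m)))
    stop_invalid("%s contains non-finite coordinates", what)
  invisible(m)
}

# Gesture label taxonomy: class 0 rest/neutral, 1 eyebrow elevation,
# 2 eye closure, 3 wide-open smile, 4 closed-mouth smile, 5 pucker.
GESTURE_LABELS <- c(
  "rest", "eyebrow_elevation", "eye_closure",
  "wide_open_smile", "closed_mouth_smile", "pucker"
)

# Palsy grade bands, mildest to most severe.
PALSY_GRADES <- c("normal", "near-normal", "mild", "moderate", "severe", "complete")

#' Gesture class labels
#'
#' Returns the fixed six-class gesture taxonomy.  Integer class codes 0-5 map
#' to these names in order.
#'
#' @return Character vector of length 6.
#' @export
gesture_labels <- function() GESTURE_LABELS

#' Palsy grade labels
#'
#' The six severity grades attached to subjects, mildest first.
#'
#' @return Character vector of length 6.
#' @export
palsy_grades <- function() PALSY_GRADES

feature_names <- function() paste0("f", 0:28)
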