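# JSON / CSV interchange for landmarks, datasets and evaluation reports.

lm_to_list <- function(lm, meta = NULL) {
  out <- list(
    points = unname(lapply(seq_len(51), function(i) as.numeric(lm$points[i, ]))),
    aux = lapply(setNames(rownames(lm$aux), rownames(lm$aux)),
                 function(nm) as.numeric(lm$aux[nm, ]))
  )
  c(out, meta)
}

lm_from_list <- function(x) {
  if (is.null(x$points) || length(x$points) != 51L)
    stop_format("landmark JSON must carry exactly 51 points")
  pts <- do.call(rbind, lapply(x$points, as.numeric))
  need <- c("chin", "left_face_side", "right_face_side")
  if (is.null(x$aux) || !all(need %in% names(x$aux)))
    stop_format("landmark JSON must carry aux points %s", paste(need, collapse = ", "))
  aux <- do.call(rbind, lapply(x$aux[need], as.numeric))
  rownames(aux) <- need
  landmark_set(pts, aux)
}

#' Write / read a single landmark set as JSON
#'
#' Format: `{"points": [[x, y] x 51], "aux": {"chin": ..., ...}}` plus any
#' metadata fields supplied in `meta` (e.g. `label`, `grade`, `subject`).
#'
#' @param lm A [landmark_set()].
#' @param path File path.
#' @param meta Optional named list of scalar metadata.
#' @return `path` (write) or a list with `landmarks` and `meta` (read).
#' @export
write_landmarks_json <- function(lm, path, meta = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  writeLines(jsonlite::toJSON(lm_to_list(lm, meta), digits = NA,
                              auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop_format("cannot parse JSON: %s",
                                                conditionMessage(e)))
  list(landmarks = lm_from_list(x),
       meta = x[setdiff(names(x), c("points", "aux"))])
}

#' Write / read a gesture dataset as JSON
#'
#' Format: `{"samples": [{<landmark fields>, "label": ..., "grade": ...,
#' "subject": ..., "origin_id": ..., "provenance": ..., "angle": ...}]}`.
#'
#' @param ds A [gesture_dataset()].
#' @param path File path.
#' @return `path` (write) or the restored [gesture_dataset()] (read).
#' @export
write_dataset_json <- function(ds, path) {
  stopifnot(inherits(ds, "gesture_dataset"))
  samples <- lapply(seq_len(length(ds)), function(i) {
    lm_to_list(ds$landmarks[[i]], as.list(ds$info[i, , drop = FALSE]))
  })
  writeLines(jsonlite::toJSON(list(samples = samples), digits = NA,
                              auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_dataset_json
#' @export
read_dataset_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop_format("cannot parse JSON: %s",
                                                conditionMessage(e)))
  if (is.null(x$samples)) stop_format("dataset JSON must carry a 'samples' array")
  landmarks <- lapply(x$samples, lm_from_list)
  meta_cols <- c("label", "grade", "subject", "origin_id", "provenance", "angle")
  defaults <- list(label = NA_integer_, grade = NA_character_,
                   subject = NA_character_, origin_id = NA_character_,
                   provenance = "original", angle = 0)
  info <- do.call(rbind, lapply(x$samples, function(s) {
    meta <- modifyList(defaults, s[setdiff(names(s), c("points", "aux"))])
    as.data.frame(meta[c(meta_cols, setdiff(names(meta), meta_cols))],
                  stringsAsFactors = FALSE)
  }))
  info$label <- as.integer(info$label)
  info$angle <- as.numeric(info$angle)
  gesture_dataset(landmarks, info)
}

#' Write / read a single landmark set as long-format CSV
#'
#' Columns `point`, `x`, `y`, one row per primary point `P0`..`P50` followed
#' by the three auxiliary points.
#'
#' @param lm A [landmark_set()].
#' @param path File path.
#' @return `path` (write) or a [landmark_set()] (read).
#' @export
write_landmarks_csv <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(point = c(rownames(lm$points), rownames(lm$aux)),
                   x = c(lm$points[, 1], lm$aux[, 1]),
                   y = c(lm$points[, 2], lm$aux[, 2]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot read CSV: %s",
                                                 conditionMessage(e)))
  if (!all(c("point", "x", "y") %in% names(df)))
    stop_format("landmark CSV needs columns point, x, y")
  prim <- paste0("P", 0:50)
  need <- c("chin", "left_face_side", "right_face_side")
  if (!all(prim %in% df$point) || !all(need %in% df$point))
    stop_format("landmark CSV must list P0..P50 and the auxiliary points")
  pts <- as.matrix(df[match(prim, df$point), c("x", "y")])
  aux <- as.matrix(df[match(need, df$point), c("x", "y")])
  rownames(aux) <- need
  landmark_set(pts, aux)
}

report_to_list <- function(rep) {
  list(accuracy = rep$accuracy,
       folds = rep$folds,
       per_class = rep$per_class,
       confusion = unname(apply(rep$confusion, 1, as.integer, simplify = FALSE)))
}

#' Write an evaluation report as JSON
#'
#' Serializes per-fold counts, overall accuracy, per-class metrics and the
#' confusion matrix (row-major, rows = actual).  A named list of reports
#' (per-grade output) is written as a JSON object keyed by grade.
#'
#' @param rep An `eval_report` or a named list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(rep, path) {
  payload <- if (inherits(rep, "eval_report")) report_to_list(rep)
             else lapply(rep, report_to_list)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              dataframe = "rows"), path)
  invisible(path)
}

#' Write a confusion matrix as CSV
#'
#' @param cm A confusion count matrix (rows = actual, columns = predicted).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  write.csv(as.data.frame(unclass(as.matrix(cm))), path, row.names = TRUE)
  invisible(path)
}
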