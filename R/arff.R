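# Attribute-Relation File Format (ARFF) interop for feature tables.
#
# Dialect: space-separated @attribute declarations, comma-separated data
# rows, no sparse format.  Numeric features are written with 17 significant
# digits so a write/read round trip preserves values to well under 1e-9.

#' Write a feature table as ARFF
#'
#' Emits `@relation` / `@attribute` / `@data` sections: 29 numeric feature
#' attributes, a nominal `label` attribute with the six class codes, and any
#' of `grade`, `subject`, `origin_id`, `provenance` present in the table as
#' string attributes.
#'
#' @param ft Feature table `data.frame` with columns `f0`..`f28` and `label`.
#' @param path Output file path.
#' @param relation Relation name.
#' @return `path`, invisibly.
#' @export
write_arff <- function(ft, path, relation = "palsy_gestures") {
  fn <- feature_names()
  if (!is.data.frame(ft) || !all(c(fn, "label") %in% names(ft)))
    stop_invalid("feature table must have columns f0..f28 and label")
  extra <- intersect(c("grade", "subject", "origin_id", "provenance"), names(ft))
  lines <- c(
    sprintf("@relation %s", relation),
    "",
    sprintf("@attribute %s numeric", fn),
    sprintf("@attribute label {%s}", paste(0:5, collapse = ",")),
    sprintf("@attribute %s string", extra),
    "",
    "@data"
  )
  num <- vapply(seq_len(nrow(ft)), function(i) {
    paste(format(as.numeric(ft[i, fn]), digits = 17, scientific = TRUE,
                 trim = TRUE),
          collapse = ",")
  }, character(1))
  rows <- paste0(num, ",", as.integer(ft$label))
  for (col in extra) rows <- paste0(rows, ",'", ft[[col]], "'")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read an ARFF feature table
#'
#' Parses the dialect written by [write_arff()] (and plain dense ARFF in
#' general: numeric, nominal and string attributes).  Malformed headers
#' raise a format error naming the offending line.
#'
#' @param path ARFF file path.
#' @return A `data.frame`; nominal `label` is returned as integer.
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(%.*)?$", raw)
  lineno <- which(keep)
  lines <- raw[keep]
  attrs <- list()
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    low <- tolower(l)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@attribute")) {
      m <- regmatches(l, regexec("^@attribute\\s+('[^']*'|\\S+)\\s+(.+)$", l,
                                 ignore.case = TRUE))[[1]]
      if (length(m) != 3L)
        stop_format("malformed @attribute on line %d", lineno[i])
      nm <- gsub("^'|'$", "", m[2])
      spec <- trimws(m[3])
      type <- if (grepl("^\\{", spec)) {
        vals <- strsplit(gsub("[{}]", "", spec), ",")[[1]]
        list(kind = "nominal", values = trimws(vals))
      } else if (tolower(spec) %in% c("numeric", "real", "integer")) {
        list(kind = "numeric")
      } else if (tolower(spec) == "string") {
        list(kind = "string")
      } else {
        stop_format("unsupported attribute type '%s' on line %d", spec, lineno[i])
      }
      attrs[[nm]] <- type
      next
    }
    if (startsWith(low, "@data")) { data_at <- i; break }
    stop_format("unexpected content before @data on line %d", lineno[i])
  }
  if (is.na(data_at)) stop_format("missing @data section")
  if (length(attrs) == 0L) stop_format("no @attribute declarations before @data")
  rows <- lines[seq_len(length(lines) - data_at) + data_at]
  parts <- strsplit(rows, ",")
  p <- length(attrs)
  bad <- which(lengths(parts) != p)
  if (length(bad))
    stop_format("row on line %d has %d fields, expected %d",
                lineno[data_at + bad[1]], lengths(parts)[bad[1]], p)
  out <- vector("list", p)
  names(out) <- names(attrs)
  for (j in seq_len(p)) {
    col <- trimws(vapply(parts, `[[`, character(1), j))
    a <- attrs[[j]]
    if (a$kind == "numeric") {
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v) && any(col[is.na(v)] != "?"))
        stop_format("non-numeric value '%s' in numeric attribute '%s'",
                    col[is.na(v)][1], names(attrs)[j])
      out[[j]] <- v
    } else if (a$kind == "nominal") {
      col <- gsub("^'|'$", "", col)
      if (!all(col %in% a$values))
        stop_format("value '%s' outside nominal domain of '%s'",
                    setdiff(col, a$values)[1], names(attrs)[j])
      out[[j]] <- if (names(attrs)[j] == "label") as.integer(col) else col
    } else {
      out[[j]] <- gsub("^'|'$", "", col)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
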