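#' Construct a clinical document
#'
#' The unit of extraction and filtering: a narrative text plus a document
#' creation time (DCT) and optional structured dates (e.g. a header visit
#' date or birth date). In EHR systems the structured date does not always
#' match the letter date written in the text, which is why the anchoring
#' policy is configurable (see [anchor_context()]).
#'
#' @param doc_id opaque identifier
#' @param text the narrative text; all span offsets refer into this string
#' @param dct document creation time as a `Date` (or `"YYYY-MM-DD"`
#'   string), may be `NULL`
#' @param structured_dates optional named list of labeled `Date`s
#'   (e.g. `visit`, `birth`)
#' @param meta free key--value list (e.g. `patient_id`)
#' @return an object of class `psytimex_document`
#' @export
document <- function(doc_id, text, dct = NULL, structured_dates = NULL,
                     meta = list()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1,
            is.character(text), length(text) == 1, !is.na(text))
  if (!is.null(dct)) {
    dct <- as.Date(dct)
    if (is.na(dct)) stop("document: dct is not a valid calendar date")
  }
  if (!is.null(structured_dates))
    structured_dates <- lapply(structured_dates, as.Date)
  structure(list(doc_id = doc_id, text = text, dct = dct,
                 structured_dates = structured_dates, meta = meta),
            class = "psytimex_document")
}

#' @export
print.psytimex_document <- function(x, ...) {
  cat(sprintf("<document %s: %d chars, dct %s>\n", x$doc_id, nchar(x$text),
              if (is.null(x$dct)) "absent" else format(x$dct)))
  invisible(x)
}

# 0-based, half-open character span; validated against a text length
validate_span <- function(start, end, text_len = NULL, what = "span") {
  if (!is_count(start) || !is_count(end) || start < 0 || start >= end)
    stop(what, ": need 0 <= start < end (0-based, half-open)")
  if (!is.null(text_len) && end > text_len)
    stop(what, ": end ", end, " exceeds document length ", text_len)
  invisible(TRUE)
}

#' Construct a time expression
#'
#' A character span (0-based, half-open) with its surface text, one of the
#' five type labels and, after normalization, a value. Temporal
#' prepositions recognized by the ruleset (since/until/for/in/at, ...) are
#' kept inside the span, which makes the Date/Duration decision explicit.
#'
#' @param start,end character offsets into the document text
#' @param surface the document substring at `[start, end)`
#' @param type one of [TIMEX_TYPES]
#' @param value a `psytimex_value`, or `NULL` before normalization
#' @param meta free key--value list (rule name, normalization hints,
#'   frequency multiplier, ...)
#' @export
time_expression <- function(start, end, surface, type, value = NULL,
                            meta = list()) {
  validate_span(start, end, what = "time_expression")
  type <- match.arg(type, TIMEX_TYPES)
  stopifnot(is.character(surface), length(surface) == 1)
  if (nchar(surface) != end - start)
    stop("time_expression: surface length does not match span width")
  if (!is.null(value)) stopifnot(inherits(value, "psytimex_value"))
  structure(list(start = as.integer(start), end = as.integer(end),
                 surface = surface, type = type, value = value, meta = meta),
            class = "psytimex_timex")
}

#' @export
print.psytimex_timex <- function(x, ...) {
  cat(sprintf("<timex [%d,%d) %s \"%s\"%s>\n", x$start, x$end, x$type,
              x$surface,
              if (is.null(x$value)) "" else paste0(" = ", serialize_value(x$value))))
  invisible(x)
}

#' Construct an annotation set
#'
#' All time expressions of one document, sorted by start offset.
#'
#' @param doc_id the document the expressions belong to
#' @param expressions list of [time_expression()] objects
#' @param doc optional `psytimex_document` used to validate spans and
#'   surface copies
#' @export
annotation_set <- function(doc_id, expressions = list(), doc = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1, is.list(expressions))
  for (e in expressions) stopifnot(inherits(e, "psytimex_timex"))
  if (!is.null(doc)) {
    stopifnot(identical(doc$doc_id, doc_id))
    n <- nchar(doc$text)
    for (e in expressions) {
      validate_span(e$start, e$end, n, "annotation_set")
      got <- substr(doc$text, e$start + 1, e$end)
      if (!identical(got, e$surface))
        stop("annotation_set: surface mismatch at [", e$start, ",", e$end,
             "): \"", e$surface, "\" vs document \"", got, "\"")
    }
  }
  if (length(expressions) > 1) {
    ord <- order(vapply(expressions, `[[`, integer(1), "start"),
                 vapply(expressions, `[[`, integer(1), "end"))
    expressions <- expressions[ord]
  }
  structure(list(doc_id = doc_id, expressions = expressions),
            class = "psytimex_annotations")
}

#' @export
length.psytimex_annotations <- function(x) length(x$expressions)

#' @export
print.psytimex_annotations <- function(x, ...) {
  cat(sprintf("<annotations %s: %d expressions>\n", x$doc_id,
              length(x$expressions)))
  invisible(x)
}

#' Tabulate an annotation set
#'
#' @param x a `psytimex_annotations` object
#' @param row.names,optional,... ignored (S3 signature)
#' @return a data frame with columns `doc_id`, `start`, `end`, `surface`,
#'   `type`, `value` (canonical string or `NA` when unnormalized)
#' @export
as.data.frame.psytimex_annotations <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  es <- x$expressions
  data.frame(
    doc_id = rep(x$doc_id, length(es)),
    start = vapply(es, `[[`, integer(1), "start"),
    end = vapply(es, `[[`, integer(1), "end"),
    surface = vapply(es, `[[`, character(1), "surface"),
    type = vapply(es, `[[`, character(1), "type"),
    value = vapply(es, function(e)
      if (is.null(e$value)) NA_character_ else serialize_value(e$value),
      character(1)),
    stringsAsFactors = FALSE)
}
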