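MONTH_RE <- paste0(
  "(?:jan(?:uary)?|feb(?:ruary)?|mar(?:ch)?|apr(?:il)?|may|jun(?:e)?|",
  "jul(?:y)?|aug(?:ust)?|sep(?:t(?:ember)?)?|oct(?:ober)?|nov(?:ember)?|",
  "dec(?:ember)?)")
WDAY_RE <- "(?:mon|tues?|wednes|thurs?|fri|satur|sun)day"

#' Load an extraction ruleset
#'
#' Rules live in a tab-separated file with columns `name`, `type`,
#' `priority`, `hints`, `pattern` (see the packaged
#' `extdata/default_rules.tsv`). Patterns are PCRE fragments, matched
#' case-insensitively; `<MONTH>` and `<WDAY>` expand to month/weekday
#' alternations and every pattern is wrapped in alphanumeric-boundary
#' lookarounds, so rules always match whole words. Higher `priority`
#' breaks ties between equal-length overlapping candidates.
#'
#' @param path path to a ruleset TSV; defaults to the packaged ruleset
#' @return a `psytimex_ruleset` (a data frame of rules)
#' @export
load_ruleset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_rules.tsv", package = "psytimex",
                        mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  need <- c("name", "type", "priority", "hints", "pattern")
  if (!all(need %in% names(df)))
    stop("load_ruleset: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$name)) stop("load_ruleset: duplicate rule names")
  bad <- setdiff(unique(df$type), TIMEX_TYPES)
  if (length(bad)) stop("load_ruleset: unknown types: ", paste(bad, collapse = ", "))
  pat <- gsub("<MONTH>", MONTH_RE, df$pattern, fixed = TRUE)
  pat <- gsub("<WDAY>", WDAY_RE, pat, fixed = TRUE)
  df$regex <- paste0("(?<![A-Za-z0-9])(?:", pat, ")(?![A-Za-z0-9])")
  df$priority <- as.integer(df$priority)
  structure(df, class = c("psytimex_ruleset", "data.frame"))
}

the_default_ruleset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_ruleset()
    cache
  }
})

#' The packaged default ruleset
#' @return a `psytimex_ruleset`
#' @export
default_ruleset <- function() the_default_ruleset()

parse_hints <- function(s) {
  if (is.na(s) || s == "" || s == "-") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE),
                  vapply(kv, `[[`, character(1), 1))
}

#' Resolve overlapping span candidates
#'
#' Longest match wins; equal-length ties are broken by rule priority
#' (higher first), then by leftmost start. The result is sorted by start
#' and pairwise disjoint.
#'
#' @param cands data frame with columns `start`, `end` (0-based,
#'   half-open) and `priority`; extra columns are carried through
#' @return the retained rows, sorted by `start`
#' @export
resolve_overlaps <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  len <- cands$end - cands$start
  ord <- order(-len, -cands$priority, cands$start)
  cands <- cands[ord, , drop = FALSE]
  keep <- logical(nrow(cands))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cands))) {
    s <- cands$start[i]; e <- cands$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  out <- cands[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Extract time-expression spans from a document
#'
#' Runs every rule pattern over the text, resolves overlaps with
#' [resolve_overlaps()] and returns a typed (but not yet normalized)
#' annotation set. Extraction is deterministic: identical input always
#' yields identical output. Structured header dates are extracted like
#' any other date; excluding them from clinical-history reasoning is a
#' consumer concern.
#'
#' @param doc a [document()]
#' @param rules a ruleset from [load_ruleset()]
#' @return a `psytimex_annotations` object with types assigned and values
#'   absent
#' @examples
#' doc <- document("d1", "He has been unwell since 2007.")
#' as.data.frame(extract_timexes(doc))
#' @export
extract_timexes <- function(doc, rules = default_ruleset()) {
  stopifnot(inherits(doc, "psytimex_document"))
  text <- doc$text
  if (nchar(text) == 0) return(annotation_set(doc$doc_id))
  starts <- integer(0); ends <- integer(0)
  prio <- integer(0); type <- character(0); rule <- character(0)
  for (i in seq_len(nrow(rules))) {
    m <- gregexpr(rules$regex[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    starts <- c(starts, as.integer(m) - 1L)       # to 0-based
    ends <- c(ends, as.integer(m) - 1L + len)
    prio <- c(prio, rep(rules$priority[i], length(m)))
    type <- c(type, rep(rules$type[i], length(m)))
    rule <- c(rule, rep(rules$name[i], length(m)))
  }
  cands <- data.frame(start = starts, end = ends, priority = prio,
                      type = type, rule = rule, stringsAsFactors = FALSE)
  kept <- resolve_overlaps(cands)
  hints_by_rule <- stats::setNames(lapply(rules$hints, parse_hints), rules$name)
  exprs <- lapply(seq_len(nrow(kept)), function(i) {
    s <- kept$start[i]; e <- kept$end[i]
    time_expression(s, e, substr(text, s + 1, e), kept$type[i],
                    meta = list(rule = kept$rule[i],
                                hints = hints_by_rule[[kept$rule[i]]]))
  })
  annotation_set(doc$doc_id, exprs, doc = doc)
}

#' Count time expressions in a document
#'
#' Equals `length(extract_timexes(doc, rules))`; used by the
#' time-expression-count triage stage ("more than 5 time expressions").
#'
#' @inheritParams extract_timexes
#' @export
count_timexes <- function(doc, rules = default_ruleset()) {
  length(extract_timexes(doc, rules))
}
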