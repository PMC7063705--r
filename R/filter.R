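#' Default psychosis symptom keyword list
#'
#' A 26-term stand-in for the clinician-defined psychosis symptom keyword
#' list used in DUP document triage. The authoritative list is external
#' and clinician-curated; this default is a plausible substitute assembled
#' from standard psychosis symptom vocabulary and should be replaced via
#' [filter_config()] for any real study.
#'
#' @return a character vector of 26 lowercase terms
#' @export
psychosis_keywords <- function() {
  c("hallucination", "hallucinations", "delusion", "delusions",
    "paranoia", "paranoid", "psychosis", "psychotic",
    "hearing voices", "voices", "thought disorder", "disorganised",
    "grandiose", "persecutory", "ideas of reference", "thought insertion",
    "thought withdrawal", "thought broadcast", "catatonia", "derailment",
    "flat affect", "social withdrawal", "suspiciousness",
    "unusual beliefs", "perceptual disturbance", "passivity")
}

#' Document length statistics
#'
#' Character length and mean characters per line (newline-split, an empty
#' trailing line excluded). An empty document gives `(0, 0)`.
#'
#' @param doc a [document()]
#' @return named numeric vector `c(char_length =, avg_line_length =)`
#' @examples
#' doc_stats(document("d", "abc\ndefgh"))  # 9, 4
#' @export
doc_stats <- function(doc) {
  stopifnot(inherits(doc, "psytimex_document"))
  n <- nchar(doc$text)
  if (n == 0) return(c(char_length = 0, avg_line_length = 0))
  lines <- strsplit(doc$text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  c(char_length = n, avg_line_length = mean(nchar(lines)))
}

#' Count symptom keyword occurrences
#'
#' Case-insensitive whole-word occurrence count, summed over terms.
#' Multi-word terms are matched as phrases. With `substring = TRUE`
#' the word-boundary requirement is dropped (documented alternative;
#' the conservative whole-word default avoids e.g. "passivity" matching
#' inside unrelated tokens).
#'
#' @param doc a [document()] (or a plain string)
#' @param keywords character vector of lowercase terms
#' @param substring match without word boundaries
#' @return total occurrence count (integer)
#' @export
keyword_count <- function(doc, keywords = psychosis_keywords(),
                          substring = FALSE) {
  text <- if (inherits(doc, "psytimex_document")) doc$text else doc
  text <- tolower(text)
  sum(vapply(keywords, function(k) {
    pat <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(k))
    pat <- gsub(" +", "[[:space:]]+", pat)
    if (!substring) pat <- paste0("(?<![a-z0-9])", pat, "(?![a-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, integer(1)))
}

# number of distinct keyword terms present (the filter only needs >= 1,
# but reports expose both occurrences and distinct terms)
keyword_terms_present <- function(doc, keywords, substring = FALSE) {
  sum(vapply(keywords, function(k)
    keyword_count(doc, k, substring = substring) > 0, logical(1)))
}

# nearest-rank percentile: value at index ceil(p/100 * n) of the sorted data
nearest_rank <- function(x, p) {
  x <- sort(unname(x))
  x[max(1L, ceiling(p / 100 * length(x)))]
}

#' Derive length thresholds from corpus percentiles
#'
#' The triage thresholds can be re-derived from the corpus at hand
#' instead of using the fixed defaults: the 50th percentile of character
#' length and the 25th percentile of average line length, via the
#' nearest-rank method.
#'
#' @param corpus a list of [document()]s
#' @return `c(min_chars =, min_avg_line =)`
#' @export
derive_percentile_thresholds <- function(corpus) {
  if (length(corpus) == 0) stop("derive_percentile_thresholds: empty corpus")
  st <- vapply(corpus, doc_stats, numeric(2))
  c(min_chars = nearest_rank(st["char_length", ], 50),
    min_avg_line = nearest_rank(st["avg_line_length", ], 25))
}

#' Triage configuration
#'
#' Thresholds for the four-stage DUP-relevance triage. All length-type
#' thresholds are strict ("greater than"), the keyword stage requires at
#' least one term, and the time-expression stage requires strictly more
#' than `min_timex_count` expressions -- so a document of exactly 2000
#' characters, or with exactly 5 time expressions, is excluded.
#'
#' @param min_chars minimum character length (strict; default 2000)
#' @param min_avg_line_chars minimum average line length (strict;
#'   default 30)
#' @param keywords symptom keyword list (default [psychosis_keywords()])
#' @param min_timex_count time-expression count that must be exceeded
#'   (default 5)
#' @param percentile_mode derive the two length thresholds from corpus
#'   percentiles instead (see [derive_percentile_thresholds()])
#' @param substring_keywords match keywords without word boundaries
#' @param stage_order order in which the stages run; the final retained
#'   set is invariant under permutation
#' @export
filter_config <- function(min_chars = 2000, min_avg_line_chars = 30,
                          keywords = psychosis_keywords(),
                          min_timex_count = 5, percentile_mode = FALSE,
                          substring_keywords = FALSE,
                          stage_order = c("length", "keyword", "timex")) {
  stopifnot(min_chars >= 0, min_avg_line_chars >= 0, min_timex_count >= 0,
            length(keywords) >= 1)
  stage_order <- match.arg(stage_order, c("length", "keyword", "timex"),
                           several.ok = TRUE)
  if (!setequal(stage_order, c("length", "keyword", "timex")))
    stop("filter_config: stage_order must permute length/keyword/timex")
  structure(list(min_chars = min_chars,
                 min_avg_line_chars = min_avg_line_chars,
                 keywords = keywords, min_timex_count = min_timex_count,
                 percentile_mode = isTRUE(percentile_mode),
                 substring_keywords = isTRUE(substring_keywords),
                 stage_order = stage_order),
            class = "psytimex_filter_config")
}

#' Four-stage DUP-relevance triage
#'
#' Filters a document collection for notes likely to describe early
#' psychosis symptom onset: (1) length stage -- character length and
#' average line length strictly above their thresholds; (2) keyword
#' stage -- at least one psychosis symptom keyword; (3) time-expression
#' stage -- strictly more than `min_timex_count` extracted time
#' expressions. Each measure depends only on the document itself, so the
#' final retained set does not depend on the stage order; measures are
#' computed lazily (the expensive time-expression count only for
#' documents that survive to that stage).
#'
#' @param corpus a list of [document()]s
#' @param cfg a [filter_config()]
#' @param rules extraction ruleset for the time-expression stage
#' @return a list with `retained` (the surviving documents), `stages`
#'   (per-stage data frame: documents in/out, patients retained) and
#'   `docs` (per-document measures and pass/fail flags; measures not
#'   computed for documents dropped earlier are `NA`)
#' @export
filter_corpus <- function(corpus, cfg = filter_config(),
                          rules = default_ruleset()) {
  stopifnot(is.list(corpus), inherits(cfg, "psytimex_filter_config"))
  for (d in corpus) stopifnot(inherits(d, "psytimex_document"))
  n <- length(corpus)
  if (cfg$percentile_mode && n > 0) {
    thr <- derive_percentile_thresholds(corpus)
    cfg$min_chars <- thr[["min_chars"]]
    cfg$min_avg_line_chars <- thr[["min_avg_line"]]
  }
  ids <- vapply(corpus, `[[`, character(1), "doc_id")
  pids <- vapply(corpus, function(d)
    as.character(d$meta$patient_id %||% NA_character_), character(1))
  docs <- data.frame(doc_id = ids, patient_id = pids,
                     char_length = NA_real_, avg_line_length = NA_real_,
                     keyword_hits = NA_integer_, keyword_terms = NA_integer_,
                     timex_count = NA_integer_,
                     pass_length = NA, pass_keyword = NA, pass_timex = NA,
                     retained = FALSE, stringsAsFactors = FALSE)
  alive <- rep(TRUE, n)
  stages <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), patients_out = integer(0),
                       stringsAsFactors = FALSE)
  n_patients <- function(keep) length(unique(stats::na.omit(pids[keep])))
  for (stage in cfg$stage_order) {
    idx <- which(alive)
    if (stage == "length") {
      st <- vapply(corpus[idx], doc_stats, numeric(2))
      docs$char_length[idx] <- st["char_length", ]
      docs$avg_line_length[idx] <- st["avg_line_length", ]
      docs$pass_length[idx] <- st["char_length", ] > cfg$min_chars &
        st["avg_line_length", ] > cfg$min_avg_line_chars
      alive[idx] <- docs$pass_length[idx]
    } else if (stage == "keyword") {
      hits <- vapply(corpus[idx], keyword_count, integer(1),
                     keywords = cfg$keywords,
                     substring = cfg$substring_keywords)
      docs$keyword_hits[idx] <- hits
      docs$keyword_terms[idx] <- vapply(corpus[idx], keyword_terms_present,
                                        integer(1), keywords = cfg$keywords,
                                        substring = cfg$substring_keywords)
      docs$pass_keyword[idx] <- hits >= 1
      alive[idx] <- docs$pass_keyword[idx]
    } else {
      cnt <- vapply(corpus[idx], count_timexes, integer(1), rules = rules)
      docs$timex_count[idx] <- cnt
      docs$pass_timex[idx] <- cnt > cfg$min_timex_count
      alive[idx] <- docs$pass_timex[idx]
    }
    stages <- rbind(stages, data.frame(
      stage = stage, n_in = length(idx), n_out = sum(alive),
      patients_out = n_patients(alive), stringsAsFactors = FALSE))
  }
  docs$retained <- alive
  list(retained = corpus[alive], stages = stages, docs = docs,
       config = cfg)
}
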