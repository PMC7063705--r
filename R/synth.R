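#' Generation profile for the synthetic corpus
#'
#' Describes the statistical shape of the generated mental-health-style
#' notes. Defaults follow the corpus characteristics the package is
#' designed around: very long narratives (mean 3974 tokens per document),
#' an Age_related share of 8.9% of all expressions with Date dominant in
#' the remainder, and 37% of Date+Time expressions relative rather than
#' absolute. Values without an external reference (expressions per
#' document, vagueness shares, noise rates) are package choices,
#' documented in the methods vignette.
#'
#' @param n_docs number of documents
#' @param seed integer master seed; per-document substreams derive from
#'   `(seed, doc_index)` so generation is reproducible document by
#'   document
#' @param mean_tokens mean narrative length in tokens (default 3974)
#' @param type_mix named probability vector over the five types; must sum
#'   to 1 (default Age_related 0.089, Date dominant)
#' @param p_relative fraction of Date+Time expressions drawn from
#'   relative/deictic templates (default 0.37)
#' @param p_vague fraction of Duration/Age_related expressions drawn from
#'   vague/categorical templates (default 0.3)
#' @param p_header probability a document carries structured header dates
#'   (default 0.9)
#' @param p_keyword probability a document mentions psychosis symptom
#'   keywords at all (default 0.6, mirroring the share of long documents
#'   that survive the keyword triage stage)
#' @param canonical_only restrict surfaces to canonical template forms
#'   covered by the default ruleset (default `TRUE`); when `FALSE`,
#'   spelling-variant noise ("yrs", lowercase month abbreviations) is
#'   applied at `noise_rate`
#' @param noise_rate probability of a surface variant when
#'   `canonical_only = FALSE`
#' @export
gen_profile <- function(n_docs = 50, seed = 42, mean_tokens = 3974,
                        type_mix = c(DATE = 0.55, TIME = 0.09,
                                     DURATION = 0.171, FREQUENCY = 0.10,
                                     AGE_RELATED = 0.089),
                        p_relative = 0.37, p_vague = 0.3, p_header = 0.9,
                        p_keyword = 0.6, canonical_only = TRUE,
                        noise_rate = 0.25) {
  stopifnot(n_docs >= 1, mean_tokens > 0,
            setequal(names(type_mix), TIMEX_TYPES),
            abs(sum(type_mix) - 1) < 1e-8,
            p_relative >= 0, p_relative <= 1, p_vague >= 0, p_vague <= 1,
            p_header >= 0, p_header <= 1, p_keyword >= 0, p_keyword <= 1)
  structure(list(n_docs = n_docs, seed = as.integer(seed),
                 mean_tokens = mean_tokens, type_mix = type_mix[TIMEX_TYPES],
                 p_relative = p_relative, p_vague = p_vague,
                 p_header = p_header, p_keyword = p_keyword,
                 canonical_only = isTRUE(canonical_only),
                 noise_rate = noise_rate),
            class = "psytimex_gen_profile")
}

# filler vocabulary: deliberately free of rule trigger words (no month
# names, digits, deictics, frequency adverbs or temporal prepositions)
FILLER_WORDS <- c(
  "patient", "reported", "ongoing", "low", "mood", "with", "poor", "sleep",
  "and", "reduced", "appetite", "he", "she", "described", "feeling",
  "isolated", "from", "family", "friends", "denied", "thoughts", "of",
  "self", "harm", "mental", "state", "examination", "was", "unremarkable",
  "speech", "normal", "rate", "tone", "affect", "reactive", "insight",
  "partial", "plan", "continue", "medication", "review", "community",
  "team", "risk", "assessment", "completed", "no", "acute", "concerns",
  "engagement", "remains", "variable", "attends", "clinic", "supported",
  "by", "care", "coordinator", "housing", "stable", "college", "course",
  "background", "includes", "difficulties", "noted", "referral", "letter")

MONTH_SURFACE <- c("January", "February", "March", "April", "May", "June",
                   "July", "August", "September", "October", "November",
                   "December")

# each template returns list(surface, type, value) -- the gold value is
# computed here by plain arithmetic on the chosen slots, independently of
# the normalizer's parsing path
synth_templates <- function(profile, dct) {
  lt <- as.POSIXlt(dct)
  dy <- lt$year + 1900L; dm <- lt$mon + 1L; dd <- lt$mday
  noisy <- function() !profile$canonical_only &&
    stats::runif(1) < profile$noise_rate
  month_surface <- function(m) {
    nm <- MONTH_SURFACE[m]
    if (noisy()) tolower(substr(nm, 1, 3)) else nm
  }
  rand_year <- function() sample(1990:(dy - 1), 1)
  list(
    DATE = list(
      absolute = function() {
        y <- rand_year(); m <- sample(1:12, 1)
        if (stats::runif(1) < 0.5) {
          list(surface = paste(month_surface(m), y), type = "DATE",
               value = sprintf("%04d-%02d", y, m))
        } else {
          d <- sample(1:28, 1)
          list(surface = paste(d, month_surface(m), y), type = "DATE",
               value = sprintf("%04d-%02d-%02d", y, m, d))
        }
      },
      year = function() {
        y <- rand_year()
        list(surface = as.character(y), type = "DATE",
             value = sprintf("%04d", y))
      },
      relative = function() {
        pick <- sample(4, 1)
        if (pick == 1) {
          list(surface = "today", type = "DATE",
               value = sprintf("%04d-%02d-%02d", dy, dm, dd))
        } else if (pick == 2) {
          d2 <- as.POSIXlt(dct - 1)
          list(surface = "yesterday", type = "DATE",
               value = sprintf("%04d-%02d-%02d", d2$year + 1900L,
                               d2$mon + 1L, d2$mday))
        } else if (pick == 3) {
          n <- sample(1:9, 1)
          unit <- if (noisy()) "yrs" else "years"
          suf <- sample(c("ago", "back"), 1)
          list(surface = paste(n, unit, suf), type = "DATE",
               value = sprintf("%04d", dy - n))
        } else {
          n <- sample(1:11, 1)
          tot <- dy * 12L + (dm - 1L) - n
          list(surface = paste(n, "months ago"), type = "DATE",
               value = sprintf("%04d-%02d", tot %/% 12L, tot %% 12L + 1L))
        }
      },
      vague = function() {
        if (stats::runif(1) < 0.5)
          list(surface = "in the past", type = "DATE", value = "PAST_REF")
        else
          list(surface = sample(c("now", "currently"), 1), type = "DATE",
               value = "PRESENT_REF")
      }
    ),
    TIME = list(
      clock = function() {
        h12 <- sample(1:12, 1); ap <- sample(c("am", "pm"), 1)
        h24 <- (h12 %% 12L) + if (ap == "pm") 12L else 0L
        list(surface = paste0("at ", h12, " ", ap), type = "TIME",
             value = sprintf("%04d-%02d-%02dT%02d:00", dy, dm, dd, h24))
      },
      daypart = function() {
        pick <- sample(4, 1)
        list(surface = c("in the morning", "in the afternoon",
                         "in the evening", "at night")[pick],
             type = "TIME", value = DAY_PARTS[pick])
      }
    ),
    DURATION = list(
      period = function() {
        n <- sample(1:9, 1)
        u <- sample(c("years", "months", "weeks", "days"), 1)
        list(surface = paste("for", n, u), type = "DURATION",
             value = paste0("P", n, toupper(substr(u, 1, 1))))
      },
      bounded = function() {
        y <- rand_year()
        b <- sample(c("since", "until"), 1)
        list(surface = paste(b, y), type = "DURATION",
             value = paste0(if (b == "since") "SIN" else "UNT", y))
      },
      range = function() {
        pick <- function(x) x[sample.int(length(x), 1)]  # no 1:n collapse
        y1 <- pick(1990:(dy - 2)); y2 <- pick((y1 + 1):(dy - 1))
        list(surface = paste0(y1, "-", y2), type = "DURATION",
             value = sprintf("(%d, %d)", y1, y2))
      },
      vague = function() {
        pick <- sample(3, 1)
        list(surface = c("for hours", "for many years",
                         "for several weeks")[pick],
             type = "DURATION", value = c("PXH", "PXY", "PXW")[pick])
      }
    ),
    FREQUENCY = list(
      times_per = function() {
        cnt <- sample(c("once", "twice"), 1)
        u <- sample(c("day", "week"), 1)
        list(surface = paste(cnt, "a", u), type = "FREQUENCY",
             value = paste0("P1", toupper(substr(u, 1, 1))))
      },
      adverb = function() {
        pick <- sample(3, 1)
        list(surface = c("daily", "weekly", "monthly")[pick],
             type = "FREQUENCY", value = c("P1D", "P1W", "P1M")[pick])
      }
    ),
    AGE_RELATED = list(
      numeric = function() {
        pick <- sample(4, 1)
        n <- sample(5:60, 1)
        switch(pick,
          list(surface = paste("a", n, "year old"), type = "AGE_RELATED",
               value = paste0("P", n, "Y")),
          list(surface = paste("aged", n), type = "AGE_RELATED",
               value = paste0("P", n, "Y")),
          list(surface = paste("when he was", min(n, 30)),
               type = "AGE_RELATED", value = paste0("A", min(n, 30), "Y")),
          list(surface = paste("at age", min(n, 30)), type = "AGE_RELATED",
               value = paste0("A", min(n, 30), "Y")))
      },
      categorical = function() {
        pick <- sample(4, 1)
        switch(pick,
          list(surface = "in his teens", type = "AGE_RELATED",
               value = "TEENS_REF"),
          list(surface = "since his teens", type = "AGE_RELATED",
               value = "SINTEENS_REF"),
          list(surface = "when she was a child", type = "AGE_RELATED",
               value = "CHILD_REF"),
          list(surface = "during childhood", type = "AGE_RELATED",
               value = "CHILD_REF"))
      }
    )
  )
}

draw_expression <- function(tpl, type, profile) {
  fams <- tpl[[type]]
  if (type == "DATE") {
    if (stats::runif(1) < profile$p_relative) return(fams$relative())
    pick <- stats::runif(1)
    if (pick < 0.12) return(fams$vague())
    if (pick < 0.35) return(fams$year())
    return(fams$absolute())
  }
  if (type == "TIME") {
    if (stats::runif(1) < profile$p_relative) return(fams$daypart())
    return(fams$clock())
  }
  if (type == "DURATION") {
    if (stats::runif(1) < profile$p_vague) return(fams$vague())
    pick <- stats::runif(1)
    if (pick < 0.4) return(fams$bounded())
    if (pick < 0.55) return(fams$range())
    return(fams$period())
  }
  if (type == "FREQUENCY") {
    if (stats::runif(1) < 0.5) return(fams$times_per())
    return(fams$adverb())
  }
  if (stats::runif(1) < profile$p_vague) return(fams$categorical())
  fams$numeric()
}

#' Generate one synthetic note with gold annotations
#'
#' Builds a clinical-style narrative: optional structured header dates
#' (visit date, date of birth), then past-history and current-state
#' paragraphs of neutral filler interleaved with time expressions drawn
#' from the template inventory. Every embedded expression is recorded in
#' the gold annotation set with its exact span, type and value (computed
#' from the chosen slots, not by running the normalizer). Deterministic
#' given `(profile$seed, doc_index)`.
#'
#' @param profile a [gen_profile()]
#' @param doc_index 1-based document index (also drives the substream)
#' @return `list(doc = <document>, gold = <annotations>)`
#' @export
generate_note <- function(profile, doc_index = 1) {
  stopifnot(inherits(profile, "psytimex_gen_profile"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((profile$seed %% 100003L) * 20011L + doc_index %% 20011L)

  dct <- as.Date("2005-01-01") + sample(0:5478, 1)   # 2005..2019
  tpl <- synth_templates(profile, dct)
  n_tok <- max(60L, stats::rpois(1, profile$mean_tokens))
  # expression density tracks document length: roughly one expression per
  # 50 tokens of narrative (long assessment letters are timex-rich)
  n_tx <- max(1L, stats::rpois(1, n_tok / 50))
  types <- sample(TIMEX_TYPES, n_tx, replace = TRUE, prob = profile$type_mix)

  chunks <- character(0)
  pos <- 0L
  exprs <- list()
  app <- function(s) {
    chunks[[length(chunks) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  filler <- function(k) {
    if (k <= 0) return(invisible())
    w <- sample(FILLER_WORDS, k, replace = TRUE)
    app(paste0(paste(w, collapse = " "), " "))
  }

  header <- stats::runif(1) < profile$p_header
  dob <- NULL
  if (header) {
    lt <- as.POSIXlt(dct)
    app(sprintf("Date of visit: %d %s %d\n", lt$mday,
                MONTH_SURFACE[lt$mon + 1L], lt$year + 1900L))
    vstart <- 15L
    vsurf <- sprintf("%d %s %d", lt$mday, MONTH_SURFACE[lt$mon + 1L],
                     lt$year + 1900L)
    exprs[[length(exprs) + 1L]] <- time_expression(
      vstart, vstart + nchar(vsurf), vsurf, "DATE",
      value = parse_value(format(dct, "%Y-%m-%d")),
      meta = list(gold_value = format(dct, "%Y-%m-%d"), header = TRUE))
    dob <- as.Date("1960-01-01") + sample(0:12000, 1)
    dsurf <- format(dob, "%d/%m/%Y")
    app("DOB: ")
    dstart <- pos
    app(dsurf)
    app("\n\n")
    exprs[[length(exprs) + 1L]] <- time_expression(
      dstart, dstart + nchar(dsurf), dsurf, "DATE",
      value = parse_value(format(dob, "%Y-%m-%d")),
      meta = list(gold_value = format(dob, "%Y-%m-%d"), header = TRUE))
  }

  kws <- if (stats::runif(1) < profile$p_keyword)
    sample(psychosis_keywords(), sample(1:4, 1), replace = TRUE) else
    character(0)
  kw_slots <- if (length(kws)) sample(n_tx, length(kws), replace = TRUE) else
    integer(0)

  gap <- max(3L, round(n_tok / max(1L, n_tx)))
  for (i in seq_len(n_tx)) {
    filler(sample(max(3L, gap - 10L):(gap + 10L), 1))
    for (k in which(kw_slots == i)) app(paste0(kws[k], " "))
    e <- draw_expression(tpl, types[i], profile)
    s <- pos
    app(e$surface)
    exprs[[length(exprs) + 1L]] <- time_expression(
      s, s + nchar(e$surface), e$surface, e$type,
      value = parse_value(e$value, type = e$type),
      meta = list(gold_value = e$value))
    app(sample(c(". ", ", ", ". \n\n"), 1, prob = c(0.6, 0.25, 0.15)))
  }
  filler(sample(5:15, 1))
  app(".")

  doc <- document(sprintf("synth%05d", doc_index), paste(chunks, collapse = ""),
                  dct = dct,
                  structured_dates = if (header) list(visit = dct, birth = dob),
                  meta = list(patient_id = sprintf("p%04d",
                                                   (doc_index - 1L) %/% 3L + 1L)))
  gold <- annotation_set(doc$doc_id, exprs, doc = doc)
  list(doc = doc, gold = gold)
}

#' Generate a synthetic corpus
#'
#' @param profile a [gen_profile()]
#' @return `list(docs = <list of documents>, gold = <list of annotation
#'   sets>)`, one element per document
#' @export
generate_corpus <- function(profile = gen_profile()) {
  notes <- lapply(seq_len(profile$n_docs), function(i)
    generate_note(profile, i))
  list(docs = lapply(notes, `[[`, "doc"),
       gold = lapply(notes, `[[`, "gold"))
}

#' Simulate a second annotator
#'
#' Perturbs a gold annotation set to emulate inter-annotator
#' disagreement: drops expressions with probability `deletion_rate`,
#' jitters span boundaries by up to `boundary_jitter` characters (always
#' keeping at least one character of overlap with the original span),
#' and rewrites values with probability `value_error_rate` (years are
#' bumped by one, other values swapped for a guaranteed-different one).
#' With all rates zero the set is returned unchanged.
#'
#' @param gold a `psytimex_annotations` object
#' @param doc the corresponding [document()]; required when
#'   `boundary_jitter > 0` so jittered surfaces can be re-copied from the
#'   text
#' @param deletion_rate,boundary_jitter,value_error_rate perturbation
#'   knobs; rates in `[0, 1]`, jitter a non-negative character count
#' @param seed integer seed
#' @return a perturbed `psytimex_annotations` object
#' @export
simulate_second_annotator <- function(gold, doc = NULL, deletion_rate = 0,
                                      boundary_jitter = 0,
                                      value_error_rate = 0, seed = 1) {
  stopifnot(inherits(gold, "psytimex_annotations"),
            deletion_rate >= 0, deletion_rate <= 1,
            value_error_rate >= 0, value_error_rate <= 1,
            boundary_jitter >= 0)
  if (boundary_jitter > 0 && is.null(doc))
    stop("simulate_second_annotator: boundary jitter needs the document")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_text <- if (is.null(doc)) NULL else nchar(doc$text)
  out <- list()
  for (e in gold$expressions) {
    if (stats::runif(1) < deletion_rate) next
    if (boundary_jitter > 0) {
      js <- sample(-boundary_jitter:boundary_jitter, 1)
      je <- sample(-boundary_jitter:boundary_jitter, 1)
      s <- max(0L, min(e$start + js, e$end - 1L))
      en <- min(n_text, max(e$end + je, e$start + 1L))
      if (s >= en) { s <- e$start; en <- e$end }
      e$start <- as.integer(s); e$end <- as.integer(en)
      e$surface <- substr(doc$text, s + 1, en)
    }
    if (!is.null(e$value) && stats::runif(1) < value_error_rate) {
      v <- serialize_value(e$value)
      v2 <- if (grepl("[0-9]{4}", v)) {
        y <- regmatches(v, regexpr("[0-9]{4}", v))
        sub(y, as.character(as.integer(y) + 1L), v, fixed = TRUE)
      } else if (grepl("[0-9]", v)) {
        d <- regmatches(v, regexpr("[0-9]+", v))
        sub(d, as.character(as.integer(d) + 1L), v, fixed = TRUE)
      } else {
        if (identical(v, "OTHER_REF")) "PAST_REF" else "OTHER_REF"
      }
      e$value <- raw_value(v2)
      e$meta$value_corrupted <- TRUE
    }
    out[[length(out) + 1L]] <- e
  }
  annotation_set(gold$doc_id, out)
}
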