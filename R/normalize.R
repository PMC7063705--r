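#' Anchoring context for normalization
#'
#' Relative expressions ("2 yrs back", "today", "last week") are resolved
#' against an anchor date, normally the document creation time (DCT). In
#' EHR exports the structured document date does not always match the
#' letter date written in the text, so the anchor policy is configurable:
#'
#' * `"STRUCTURED"` (default): use the structured DCT supplied with the
#'   document;
#' * `"FIRST_IN_TEXT_DATE"`: use the first fully specified date written
#'   in the text (see [anchor_for_document()]);
#' * `"OVERRIDE"`: use an explicitly supplied date.
#'
#' When no anchor is available, relative expressions normalize to
#' placeholder calendar values (`"XXXX"`, ...) rather than being dropped.
#' A running anchor (re-anchoring to previously mentioned dates) is
#' deliberately not applied by default; `last_resolved_date` is carried
#' for consumers that opt in via `update_anchor`.
#'
#' @param dct anchor date (`Date` or `"YYYY-MM-DD"`), may be `NULL`
#' @param dct_policy one of `"STRUCTURED"`, `"FIRST_IN_TEXT_DATE"`,
#'   `"OVERRIDE"` (informational; see [anchor_for_document()])
#' @param date_order interpretation of ambiguous numeric dates:
#'   `"DMY"` (U.K., default) or `"MDY"` (U.S.)
#' @param last_resolved_date optional running anchor
#' @param update_anchor whether to update the running anchor as dates
#'   resolve (off by default)
#' @export
anchor_context <- function(dct = NULL,
                           dct_policy = c("STRUCTURED", "FIRST_IN_TEXT_DATE",
                                          "OVERRIDE"),
                           date_order = c("DMY", "MDY"),
                           last_resolved_date = NULL,
                           update_anchor = FALSE) {
  if (!is.null(dct)) dct <- as.Date(dct)
  structure(list(dct = dct, dct_policy = match.arg(dct_policy),
                 date_order = match.arg(date_order),
                 last_resolved_date = last_resolved_date,
                 update_anchor = isTRUE(update_anchor)),
            class = "psytimex_anchor")
}

#' Select the anchor date for a document
#'
#' Applies the DCT policy: `"STRUCTURED"` uses the document's `dct` field
#' (falling back to a structured `visit` date); `"FIRST_IN_TEXT_DATE"`
#' extracts dates from the text and uses the first one that resolves to a
#' full calendar date; `"OVERRIDE"` uses `override`.
#'
#' @param doc a [document()]
#' @param policy anchor policy (see [anchor_context()])
#' @param rules ruleset used when scanning the text for dates
#' @param override explicit anchor date for the `"OVERRIDE"` policy
#' @return a `Date`, or `NULL` when no anchor can be found
#' @export
anchor_for_document <- function(doc, policy = "STRUCTURED",
                                rules = default_ruleset(), override = NULL) {
  policy <- match.arg(policy, c("STRUCTURED", "FIRST_IN_TEXT_DATE", "OVERRIDE"))
  if (policy == "OVERRIDE") {
    if (is.null(override)) stop("anchor_for_document: OVERRIDE needs a date")
    return(as.Date(override))
  }
  if (policy == "STRUCTURED") {
    if (!is.null(doc$dct)) return(doc$dct)
    if (!is.null(doc$structured_dates$visit)) return(doc$structured_dates$visit)
    return(NULL)
  }
  anns <- extract_timexes(doc, rules)
  for (e in anns$expressions) {
    if (e$type != "DATE") next
    v <- norm_date_surface(strip_preposition(squish(e$surface)), "DMY")
    if (!is.null(v) && v$date_known && !is.null(v$day))
      return(as.Date(sprintf("%04d-%02d-%02d", v$year, v$month, v$day)))
  }
  NULL
}

squish <- function(s) tolower(trimws(gsub("[[:space:]]+", " ", s)))

strip_preposition <- function(s) {
  sub("^(?:in|on|at|by|around|about) +", "", s, perl = TRUE)
}

MONTH_NAMES <- c("january", "february", "march", "april", "may", "june",
                 "july", "august", "september", "october", "november",
                 "december")

month_num <- function(name) {
  name <- tolower(name)
  hit <- which(substr(MONTH_NAMES, 1, 3) == substr(name, 1, 3))
  if (length(hit) != 1) return(NA_integer_)
  # reject non-prefixes like "mayx"
  if (!startsWith(MONTH_NAMES[hit], sub("\\.$", "", name))) return(NA_integer_)
  hit
}

NUM_WORDS <- c(a = 1, an = 1, one = 1, two = 2, three = 3, four = 4,
               five = 5, six = 6, seven = 7, eight = 8, nine = 9, ten = 10)

word_to_n <- function(w) {
  w <- tolower(w)
  if (grepl("^[0-9]+$", w)) return(as.integer(w))
  n <- NUM_WORDS[w]
  if (is.na(n)) NA_integer_ else as.integer(n)
}

UNIT_MAP <- c(year = "Y", years = "Y", yr = "Y", yrs = "Y",
              month = "M", months = "M",
              week = "W", weeks = "W",
              day = "D", days = "D",
              hour = "H", hours = "H", hr = "H", hrs = "H",
              min = "MIN", mins = "MIN", minute = "MIN", minutes = "MIN",
              sec = "S", secs = "S", second = "S", seconds = "S")

unit_code <- function(w) {
  u <- UNIT_MAP[tolower(w)]
  if (is.na(u)) NA_character_ else unname(u)
}

# ---- absolute date surface parsing ------------------------------------

two_digit_year <- function(y) if (y >= 100) y else if (y >= 30) 1900L + y else 2000L + y

# parse an absolute date surface (no leading preposition) to a calendar
# value at its stated granularity, or NULL if it is not an absolute date
norm_date_surface <- function(s, date_order = "DMY") {
  s <- sub(paste0("^", WDAY_RE, "[ ,]+"), "", s, perl = TRUE)
  m <- regmatches(s, regexec("^([0-9]{4})-([0-9]{2})-([0-9]{2})$", s))[[1]]
  if (length(m)) return(calendar_value(as.integer(m[2]), as.integer(m[3]),
                                       as.integer(m[4])))
  m <- regmatches(s, regexec("^([0-9]{4})[/.]([0-9]{1,2})[/.]([0-9]{1,2})$", s))[[1]]
  if (length(m)) return(calendar_value(as.integer(m[2]), as.integer(m[3]),
                                       as.integer(m[4])))
  m <- regmatches(s, regexec("^([0-9]{1,2})[/.]([0-9]{1,2})[/.]([0-9]{2,4})$", s))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3]); y <- two_digit_year(as.integer(m[4]))
    if (date_order == "DMY") return(calendar_value(y, b, a))
    return(calendar_value(y, a, b))
  }
  m <- regmatches(s, regexec(
    "^([0-9]{1,2})(?:st|nd|rd|th)?(?: of)? +([a-z.]+),? +([0-9]{4})$", s,
    perl = TRUE))[[1]]
  if (length(m)) {
    mo <- month_num(m[3])
    if (!is.na(mo)) return(calendar_value(as.integer(m[4]), mo, as.integer(m[2])))
  }
  m <- regmatches(s, regexec(
    "^([a-z.]+) +([0-9]{1,2})(?:st|nd|rd|th)?,? +([0-9]{4})$", s, perl = TRUE))[[1]]
  if (length(m)) {
    mo <- month_num(m[2])
    if (!is.na(mo)) return(calendar_value(as.integer(m[4]), mo, as.integer(m[3])))
  }
  m <- regmatches(s, regexec("^([a-z.]+),? +([0-9]{4})$", s, perl = TRUE))[[1]]
  if (length(m)) {
    mo <- month_num(m[2])
    if (!is.na(mo)) return(calendar_value(as.integer(m[3]), mo))
  }
  m <- regmatches(s, regexec("^([0-9]{4})$", s))[[1]]
  if (length(m)) return(calendar_value(as.integer(m[2])))
  NULL
}

# ---- relative date resolution -----------------------------------------

cal_from_date <- function(d, granularity = "D") {
  lt <- as.POSIXlt(d)
  switch(granularity,
         Y = calendar_value(lt$year + 1900L),
         M = calendar_value(lt$year + 1900L, lt$mon + 1L),
         D = calendar_value(lt$year + 1900L, lt$mon + 1L, lt$mday))
}

shift_months <- function(d, k) {
  lt <- as.POSIXlt(d)
  tot <- (lt$year + 1900L) * 12L + lt$mon + k
  c(year = tot %/% 12L, month = tot %% 12L + 1L)
}

monday_of_week <- function(d) {
  wd <- as.POSIXlt(d)$wday            # 0 = Sunday
  d - ((wd + 6L) %% 7L)
}

#' Resolve a relative date expression against the anchor
#'
#' Handles deictics (today/yesterday/tomorrow), "n units ago/back/earlier"
#' and "last/next/this unit" forms. The output granularity equals the
#' coarsest unit mentioned: years give `"YYYY"`, months `"YYYY-MM"`,
#' weeks and days a full date ("last week" resolves to the Monday of the
#' preceding ISO week). With no anchor available the result is a
#' placeholder calendar value at the same granularity.
#'
#' @param surface the relative expression surface text
#' @param ctx an [anchor_context()]
#' @return a calendar `psytimex_value`, or `NULL` if the surface is not a
#'   recognized relative pattern
#' @export
resolve_relative <- function(surface, ctx = anchor_context()) {
  s <- strip_preposition(squish(surface))
  dct <- ctx$dct
  unknown <- function(g) calendar_value(date_known = FALSE, granularity = g)
  if (s %in% c("today", "tonight")) {
    return(if (is.null(dct)) unknown("D") else cal_from_date(dct))
  }
  if (s == "yesterday")
    return(if (is.null(dct)) unknown("D") else cal_from_date(dct - 1))
  if (s == "tomorrow")
    return(if (is.null(dct)) unknown("D") else cal_from_date(dct + 1))
  m <- regmatches(s, regexec(
    "^(?:(?:about|around|almost|over|nearly) +)?([a-z0-9]+) +([a-z]+) +(?:ago|back|earlier)$",
    s, perl = TRUE))[[1]]
  if (length(m)) {
    n <- word_to_n(m[2]); u <- unit_code(m[3])
    if (!is.na(n) && !is.na(u)) {
      if (u == "Y") {
        if (is.null(dct)) return(unknown("Y"))
        return(calendar_value(as.POSIXlt(dct)$year + 1900L - n))
      }
      if (u == "M") {
        if (is.null(dct)) return(unknown("M"))
        ym <- shift_months(dct, -n)
        return(calendar_value(ym[["year"]], ym[["month"]]))
      }
      if (u == "W") {
        if (is.null(dct)) return(unknown("D"))
        return(cal_from_date(dct - 7L * n))
      }
      if (u == "D") {
        if (is.null(dct)) return(unknown("D"))
        return(cal_from_date(dct - n))
      }
    }
  }
  m <- regmatches(s, regexec("^(last|next|this) +([a-z]+)$", s, perl = TRUE))[[1]]
  if (length(m)) {
    dir <- switch(m[2], last = -1L, next_ = 1L, `next` = 1L, this = 0L)
    w <- m[3]
    if (w == "year") {
      if (is.null(dct)) return(unknown("Y"))
      return(calendar_value(as.POSIXlt(dct)$year + 1900L + dir))
    }
    if (w == "month") {
      if (is.null(dct)) return(unknown("M"))
      ym <- shift_months(dct, dir)
      return(calendar_value(ym[["year"]], ym[["month"]]))
    }
    if (w == "week") {
      if (is.null(dct)) return(unknown("D"))
      return(cal_from_date(monday_of_week(dct) + 7L * dir))
    }
    mo <- month_num(w)
    if (!is.na(mo)) {
      if (is.null(dct)) return(unknown("M"))
      lt <- as.POSIXlt(dct); y <- lt$year + 1900L; mc <- lt$mon + 1L
      if (dir == -1L && mo >= mc) y <- y - 1L
      if (dir == 1L && mo <= mc) y <- y + 1L
      return(calendar_value(y, mo))
    }
    if (grepl(paste0("^", WDAY_RE, "$"), w, perl = TRUE)) {
      if (is.null(dct)) return(unknown("D"))
      wd_target <- match(substr(w, 1, 3),
                         c("sun", "mon", "tue", "wed", "thu", "fri", "sat")) - 1L
      wd <- as.POSIXlt(dct)$wday
      delta <- if (dir <= 0L) -((wd - wd_target) %% 7L) else
        (wd_target - wd) %% 7L
      if (delta == 0L && dir != 0L) delta <- 7L * dir
      return(cal_from_date(dct + delta))
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# ---- per-type normalization -------------------------------------------

PAST_REF_RE <- "^(?:in the (?:distant )?past|historically|previously)$"
PRESENT_REF_RE <- paste0("^(?:(?:right )?now|currently|presently|",
                         "at (?:this|the) (?:time|moment)|at present|these days)$")

norm_date <- function(s, ctx, hints) {
  ref <- hints$ref %||% NULL
  if (!is.null(ref) && ref %in% c("PAST_REF", "PRESENT_REF"))
    return(categorical_ref(ref))
  if (grepl(PAST_REF_RE, s, perl = TRUE)) return(categorical_ref("PAST_REF"))
  if (grepl(PRESENT_REF_RE, s, perl = TRUE)) return(categorical_ref("PRESENT_REF"))
  v <- norm_date_surface(strip_preposition(s), ctx$date_order)
  if (!is.null(v)) return(v)
  v <- resolve_relative(s, ctx)
  if (!is.null(v)) return(v)
  unresolved_value()
}

norm_time <- function(s, ctx) {
  if (grepl("morning", s)) return(day_part("TMO"))
  if (grepl("afternoon", s)) return(day_part("TAF"))
  if (grepl("evening", s)) return(day_part("TEV"))
  if (grepl("night|overnight", s)) return(day_part("TNI"))
  m <- regmatches(s, regexec(
    "([0-9]{1,2})(?:[:.]([0-9]{2}))? *(am|pm|a\\.m\\.|p\\.m\\.)?", s,
    perl = TRUE))[[1]]
  if (length(m) && m[2] != "") {
    h <- as.integer(m[2])
    mi <- if (m[3] == "") 0L else as.integer(m[3])
    ap <- substr(m[4], 1, 1)
    if (ap == "" && m[3] == "") return(unresolved_value())  # bare number
    if (ap == "p" && h < 12) h <- h + 12L
    if (ap == "a" && h == 12) h <- 0L
    if (h > 23 || mi > 59) return(unresolved_value())
    if (!is.null(ctx$dct)) {
      lt <- as.POSIXlt(ctx$dct)
      return(calendar_value(lt$year + 1900L, lt$mon + 1L, lt$mday,
                            hour = h, minute = mi))
    }
    return(calendar_value(date_known = FALSE, granularity = "D",
                          hour = h, minute = mi))
  }
  unresolved_value()
}

VAGUE_UNIT <- c(hours = "H", days = "D", weeks = "W", months = "M",
                years = "Y", ages = "Y")

norm_duration <- function(s, ctx) {
  m <- regmatches(s, regexec("^(since|until|till) +(.+)$", s, perl = TRUE))[[1]]
  if (length(m)) {
    bound <- if (m[2] == "since") "SIN" else "UNT"
    rest <- m[3]
    v <- resolve_relative(rest, ctx)
    if (is.null(v)) v <- norm_date_surface(rest, ctx$date_order)
    if (is.null(v)) return(unresolved_value())
    return(bounded_interval(bound, v))
  }
  m <- regmatches(s, regexec(
    "^(?:from +)?([0-9]{4}) *(?:[–—-]|to|until|till) *([0-9]{4})$",
    s, perl = TRUE))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    if (a <= b) return(range_value(calendar_value(a), calendar_value(b)))
    return(unresolved_value())
  }
  m <- regmatches(s, regexec(paste0(
    "^(?:for +)?(?:(?:about|around|almost|over|nearly|at least) +)?",
    "([a-z0-9]+) +([a-z]+)$"), s, perl = TRUE))[[1]]
  if (length(m)) {
    n <- word_to_n(m[2]); u <- unit_code(m[3])
    if (!is.na(n) && !is.na(u)) return(period_value(n, u))
  }
  m <- regmatches(s, regexec(paste0(
    "^for +(?:(?:many|several|some|a few|a couple of) +)?",
    "(hours|days|weeks|months|years|ages)$"), s, perl = TRUE))[[1]]
  if (length(m)) {
    u <- VAGUE_UNIT[[m[2]]]
    return(period_value("X", u, clock = FALSE))
  }
  m <- regmatches(s, regexec(paste0(
    "^(?:over +|in +|during +|for +)?the +(?:past|last) +",
    "(?:(few|couple of|[0-9]+) +)?([a-z]+)$"), s, perl = TRUE))[[1]]
  if (length(m)) {
    u <- unit_code(m[3])
    if (!is.na(u)) {
      n <- if (m[2] %in% c("", "few", "couple of")) NA_integer_ else word_to_n(m[2])
      if (m[2] == "") n <- 1L
      if (is.na(n)) return(period_value("X", u, clock = FALSE))
      return(period_value(n, u))
    }
  }
  unresolved_value()
}

FREQ_ADVERB <- list(daily = c(1, "D"), nightly = c(1, "D"), weekly = c(1, "W"),
                    fortnightly = c(2, "W"), monthly = c(1, "M"),
                    yearly = c(1, "Y"), annually = c(1, "Y"),
                    hourly = c(1, "H"))
FREQ_UNIT <- c(day = "D", night = "D", morning = "D", evening = "D",
               week = "W", month = "M", year = "Y", hour = "H")

norm_frequency <- function(s) {
  adv <- FREQ_ADVERB[[s]]
  if (!is.null(adv))
    return(list(value = period_value(as.integer(adv[1]), adv[2], clock = FALSE),
                freq_count = 1L))
  m <- regmatches(s, regexec(
    "^(once|twice|thrice|[a-z0-9]+(?: times)?) +(?:a|per|every) +([a-z]+)$",
    s, perl = TRUE))[[1]]
  if (length(m)) {
    cnt <- switch(m[2], once = 1L, twice = 2L, thrice = 3L,
                  word_to_n(sub(" times$", "", m[2])))
    u <- FREQ_UNIT[m[3]]
    if (!is.na(u) && !is.na(cnt))
      return(list(value = period_value(1, unname(u), clock = FALSE),
                  freq_count = cnt))
  }
  m <- regmatches(s, regexec("^every +(other +)?([a-z]+)$", s, perl = TRUE))[[1]]
  if (length(m)) {
    u <- FREQ_UNIT[m[3]]
    if (!is.na(u)) {
      n <- if (m[2] == "") 1L else 2L
      return(list(value = period_value(n, unname(u), clock = FALSE),
                  freq_count = 1L))
    }
  }
  list(value = unresolved_value(), freq_count = NULL)
}

#' Default age lexicon
#'
#' Keyword to life-stage reference mapping used when normalizing vague
#' age-related expressions ("when he was a child", "in his teens").
#' Replace or extend by passing your own named character vector wherever
#' a `lex` argument is accepted; names are lowercase keywords, values one
#' of the six categorical age references.
#'
#' @return a named character vector
#' @export
default_age_lexicon <- function() {
  c("childhood" = "CHILD_REF", "child" = "CHILD_REF", "kid" = "CHILD_REF",
    "toddler" = "CHILD_REF", "baby" = "CHILD_REF", "boy" = "CHILD_REF",
    "girl" = "CHILD_REF",
    "adolescence" = "TEENS_REF", "adolescent" = "TEENS_REF",
    "teenager" = "TEENS_REF", "teens" = "TEENS_REF",
    "twenties" = "ADULT_REF", "thirties" = "ADULT_REF",
    "adulthood" = "ADULT_REF", "adult" = "ADULT_REF",
    "school" = "SCHOOL_REF", "student" = "SCHOOL_REF",
    "university" = "UNI_REF", "uni" = "UNI_REF", "college" = "UNI_REF")
}

check_age_lexicon <- function(lex) {
  ok <- c("CHILD_REF", "SCHOOL_REF", "TEENS_REF", "ADULT_REF", "UNI_REF",
          "OTHER_REF")
  if (!all(lex %in% ok))
    stop("age lexicon maps to non-categorical targets: ",
         paste(setdiff(lex, ok), collapse = ", "))
  invisible(lex)
}

#' Post-process an age-related expression
#'
#' Implements the age-specific normalization rules: current-age surface
#' patterns ("a 45 year old", "aged 45") give a current-age value
#' (`P45Y`); past patterns ("when he was 15", "at age 8") give a past-age
#' value (`A15Y`); lexicon keyword hits give a life-stage reference
#' ("in his teens" gives `TEENS_REF`); anything else falls back to
#' `OTHER_REF`. Bound-led forms keep the bound: "since his teens" gives
#' `SINTEENS_REF` and "since age 3 months" gives `SINA3M` (a documented
#' extension -- no canonical form is fixed for bounded ages).
#'
#' @param tx a `psytimex_timex` with `type == "AGE_RELATED"`
#' @param lex age lexicon (named character vector)
#' @return `tx` with its value filled
#' @export
postprocess_age <- function(tx, lex = default_age_lexicon()) {
  stopifnot(inherits(tx, "psytimex_timex"), tx$type == "AGE_RELATED")
  check_age_lexicon(lex)
  s <- squish(tx$surface)
  bound <- NULL
  m <- regmatches(s, regexec("^(since|until|till) +(.+)$", s, perl = TRUE))[[1]]
  if (length(m)) {
    bound <- if (m[2] == "since") "SIN" else "UNT"
    s <- m[3]
  }
  wrap <- function(v) {
    tx$value <- if (is.null(bound)) v else bounded_interval(bound, v)
    tx
  }
  # numeric ages; unit defaults to years, months recognized for infancy
  num_pats <- c(
    past_when = "^when (?:he|she|they) (?:was|were) (?:only |about |around )?([0-9]{1,3})(?: ([a-z]+) old)?$",
    past_at = "^at (?:the )?age (?:of )?([0-9]{1,3})(?: ([a-z]+))?$",
    past_at2 = "^at ([0-9]{1,3}) (years) of age$",
    past_age = "^(?:the )?age (?:of )?([0-9]{1,3})(?: ([a-z]+))?$",
    cur_old = "^(?:an? )?([0-9]{1,3})[- ]+((?:year|yr)s?)[- ]+old$",
    cur_aged = "^aged ([0-9]{1,3})$")
  for (nm in names(num_pats)) {
    m <- regmatches(s, regexec(num_pats[[nm]], s, perl = TRUE))[[1]]
    if (length(m)) {
      n <- as.integer(m[2])
      u <- if (length(m) >= 3 && !is.na(m[3]) && m[3] != "")
        unit_code(m[3]) else "Y"
      if (is.na(u) || !u %in% c("Y", "M")) u <- "Y"
      mode <- if (startsWith(nm, "cur") && is.null(bound)) "CURRENT" else "PAST"
      return(wrap(age_value(mode, n, u)))
    }
  }
  # life-stage keywords, longest keyword first
  for (kw in names(lex)[order(-nchar(names(lex)))]) {
    if (grepl(paste0("(?<![a-z])", kw, "(?![a-z])"), s, perl = TRUE))
      return(wrap(categorical_ref(unname(lex[kw]))))
  }
  wrap(categorical_ref("OTHER_REF"))
}

#' Normalize a time expression
#'
#' Assigns a normalized value according to the expression's type:
#'
#' * `DATE`: calendar value at the stated granularity, a resolved
#'   relative date, or `PAST_REF`/`PRESENT_REF` for deictic vagueness
#'   (only explicit "today" resolves to the DCT date);
#' * `TIME`: full date-time when the anchor provides the date
#'   (`"2011-03-14T18:00"`), placeholder date otherwise, or a day part;
#' * `DURATION`: a period (`P4Y`, `PT15M`, vague `PXH`), a bounded
#'   interval (`SIN2007`, `UNT2018`) or an explicit range
#'   (`"(2009, 2012)"`);
#' * `FREQUENCY`: the period template (e.g. "twice a week" gives `P1W`
#'   with the multiplier 2 stored in `meta$freq_count`);
#' * `AGE_RELATED`: see [postprocess_age()].
#'
#' Unknown surface forms receive the `UNRESOLVED` sentinel -- they are
#' never silently dropped. Deterministic given `(tx, ctx, lex)`.
#'
#' @param tx a `psytimex_timex`
#' @param ctx an [anchor_context()]
#' @param lex age lexicon (see [default_age_lexicon()])
#' @return `tx` with its value (and possibly `meta`) filled
#' @examples
#' ctx <- anchor_context(dct = "2011-03-14")
#' tx <- time_expression(0, 10, "6 pm sharp", "TIME")
#' serialize_value(normalize_timex(tx, ctx)$value)  # "2011-03-14T18:00"
#' @export
normalize_timex <- function(tx, ctx = anchor_context(),
                            lex = default_age_lexicon()) {
  stopifnot(inherits(tx, "psytimex_timex"), inherits(ctx, "psytimex_anchor"))
  s <- squish(tx$surface)
  hints <- tx$meta$hints %||% list()
  if (tx$type == "AGE_RELATED") return(postprocess_age(tx, lex))
  if (tx$type == "DATE") {
    tx$value <- norm_date(s, ctx, hints)
  } else if (tx$type == "TIME") {
    tx$value <- norm_time(s, ctx)
  } else if (tx$type == "DURATION") {
    tx$value <- norm_duration(s, ctx)
  } else if (tx$type == "FREQUENCY") {
    r <- norm_frequency(s)
    tx$value <- r$value
    if (!is.null(r$freq_count)) tx$meta$freq_count <- r$freq_count
  }
  tx
}

#' Normalize every expression of an annotation set
#'
#' @param anns a `psytimex_annotations` object
#' @inheritParams normalize_timex
#' @return the annotation set with values filled
#' @export
normalize_annotations <- function(anns, ctx = anchor_context(),
                                  lex = default_age_lexicon()) {
  stopifnot(inherits(anns, "psytimex_annotations"))
  anns$expressions <- lapply(anns$expressions, normalize_timex,
                             ctx = ctx, lex = lex)
  anns
}

#' Extract and normalize in one pass
#'
#' Convenience wrapper: selects the anchor via the DCT policy, extracts
#' spans and normalizes them.
#'
#' @param doc a [document()]
#' @param rules extraction ruleset
#' @param dct_policy anchor policy (see [anchor_context()])
#' @param date_order numeric date dialect, `"DMY"` or `"MDY"`
#' @param lex age lexicon
#' @param override explicit anchor date for the `"OVERRIDE"` policy
#' @return a normalized `psytimex_annotations` object
#' @export
tag_document <- function(doc, rules = default_ruleset(),
                         dct_policy = "STRUCTURED", date_order = "DMY",
                         lex = default_age_lexicon(), override = NULL) {
  dct <- anchor_for_document(doc, dct_policy, rules, override)
  ctx <- anchor_context(dct = dct, dct_policy = dct_policy,
                        date_order = date_order)
  normalize_annotations(extract_timexes(doc, rules), ctx, lex)
}

#' Default life-stage age ranges
#'
#' Past-age (start, end) pairs for the categorical life-stage references,
#' used to turn vague references into bounded onset estimates for
#' DUP-style reasoning. Only the teens range is conventional
#' ((A13Y, A19Y)); the others are package defaults, not authoritative,
#' and should be overridden to match a study's definitions.
#'
#' @return a named list of `c(start, end)` integer year pairs
#' @export
default_age_ranges <- function() {
  list(CHILD_REF = c(0L, 12L), SCHOOL_REF = c(5L, 18L),
       TEENS_REF = c(13L, 19L), UNI_REF = c(18L, 22L),
       ADULT_REF = c(18L, 65L))
}

#' Map a life-stage reference to a past-age range
#'
#' @param ref a categorical reference code (e.g. `"TEENS_REF"`)
#' @param ranges mapping table as from [default_age_ranges()]
#' @return a list of two past-age values `(start, end)`, e.g.
#'   `TEENS_REF` gives (`A13Y`, `A19Y`); `NULL` for `OTHER_REF` and the
#'   non-life-stage references (no range is defined)
#' @export
age_ref_to_range <- function(ref, ranges = default_age_ranges()) {
  ref <- match.arg(ref, CATEGORICAL_REFS)
  r <- ranges[[ref]]
  if (is.null(r)) return(NULL)
  list(start = age_value("PAST", r[1]), end = age_value("PAST", r[2]))
}
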