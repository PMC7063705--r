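#' @title Normalized time-expression values
#'
#' @description
#' Time expressions are normalized to a tagged union of value variants,
#' each with a canonical string form:
#'
#' * calendar values: `"2011"`, `"2011-05"`, `"2011-05-03"`,
#'   `"2011-05-03T18:00"`, or placeholder dates `"XXXX-XX-XXT18:00"` when
#'   the date part is unknown;
#' * day parts: `"TMO"`, `"TAF"`, `"TEV"`, `"TNI"`;
#' * periods (durations/frequencies): `"P4Y"`, `"PT15M"`, vague `"PXH"`;
#' * bounded intervals: `"SIN2007"`, `"UNT2018"` (anchor may also be a
#'   life-stage reference or a past-age value, e.g. `"SINTEENS_REF"`);
#' * ranges: `"(2009, 2012)"`;
#' * age values: current age `"P45Y"`, past age `"A15Y"`;
#' * categorical references: `"PAST_REF"`, `"PRESENT_REF"`, `"CHILD_REF"`,
#'   `"SCHOOL_REF"`, `"TEENS_REF"`, `"ADULT_REF"`, `"UNI_REF"`, `"OTHER_REF"`;
#' * the `"UNRESOLVED"` sentinel for surface forms the ruleset cannot
#'   normalize (never silently dropped).
#'
#' A `"P45Y"` string is ambiguous between a 45-year duration and a
#' current-age value; [parse_value()] disambiguates only via the `type`
#' argument (the carrying expression's type), never by string inspection.
#'
#' @name normalized-values
NULL

#' Time-expression type labels
#'
#' The five expression types: `DATE`, `TIME`, `DURATION`, `FREQUENCY` and
#' the mental-health-specific `AGE_RELATED` (age-anchored references such
#' as "at age 8" or "in his teens").
#'
#' @export
TIMEX_TYPES <- c("DATE", "TIME", "DURATION", "FREQUENCY", "AGE_RELATED")

#' Categorical reference codes
#' @export
CATEGORICAL_REFS <- c("PAST_REF", "PRESENT_REF", "CHILD_REF", "SCHOOL_REF",
                      "TEENS_REF", "ADULT_REF", "UNI_REF", "OTHER_REF")

#' Day-part codes (morning, afternoon, evening, night)
#' @export
DAY_PARTS <- c("TMO", "TAF", "TEV", "TNI")

PERIOD_UNITS <- c("Y", "M", "W", "D", "H", "MIN", "S")

new_value <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "psytimex_value")
}

#' @export
print.psytimex_value <- function(x, ...) {
  cat(sprintf("<value %s: %s>\n", x$kind, serialize_value(x)))
  invisible(x)
}

is_count <- function(x) {
  length(x) == 1 && !is.na(x) && is.numeric(x) && x == as.integer(x)
}

#' Construct a calendar value
#'
#' A (partial) calendar date with optional clock time. Granularity follows
#' the fields given: year, year-month, full date, and optionally `Thh:mm`.
#' When `date_known = FALSE` the date part renders as placeholders
#' (`"XXXX"`, `"XXXX-XX"` or `"XXXX-XX-XX"` according to `granularity`).
#'
#' @param year,month,day integer date components (progressively optional)
#' @param hour,minute clock time; `minute` defaults to 0 when `hour` given
#' @param date_known if `FALSE` the date part is unknown and rendered as
#'   placeholders; `year`/`month`/`day` must then be absent
#' @param granularity placeholder granularity when `date_known = FALSE`:
#'   one of `"Y"`, `"M"`, `"D"`
#' @return a `psytimex_value` of kind `"calendar"`
#' @export
calendar_value <- function(year = NULL, month = NULL, day = NULL,
                           hour = NULL, minute = NULL,
                           date_known = TRUE, granularity = "D") {
  if (date_known) {
    if (!is_count(year)) stop("calendar_value: year required when date_known")
    if (!is.null(day) && is.null(month)) stop("calendar_value: day without month")
    if (!is.null(month) && (month < 1 || month > 12)) stop("calendar_value: bad month")
    if (!is.null(day) && (day < 1 || day > 31)) stop("calendar_value: bad day")
  } else {
    if (!is.null(year) || !is.null(month) || !is.null(day))
      stop("calendar_value: date fields given with date_known = FALSE")
    if (!granularity %in% c("Y", "M", "D")) stop("calendar_value: bad granularity")
  }
  if (!is.null(hour)) {
    if (is.null(minute)) minute <- 0L
    if (hour < 0 || hour > 23 || minute < 0 || minute > 59)
      stop("calendar_value: bad time")
  } else if (!is.null(minute)) {
    stop("calendar_value: minute without hour")
  }
  as_int <- function(x) if (is.null(x)) NULL else as.integer(x)
  new_value("calendar", list(
    year = as_int(year), month = as_int(month), day = as_int(day),
    hour = as_int(hour), minute = as_int(minute),
    date_known = isTRUE(date_known),
    granularity = if (date_known) NULL else granularity))
}

#' Construct a day-part value
#' @param code one of `"TMO"`, `"TAF"`, `"TEV"`, `"TNI"`
#' @export
day_part <- function(code) {
  code <- match.arg(code, DAY_PARTS)
  new_value("day_part", list(code = code))
}

#' Construct a period (duration) value
#'
#' Periods render as `P<count><unit>`, with a `T` marker before the unit
#' when `clock` is `TRUE` (sub-day clock units). Minutes (`"MIN"`) and
#' seconds require the clock marker so `"P3M"` (3 months) and `"PT3M"`
#' (3 minutes) stay distinct. Vague counts use the placeholder `"X"`
#' (e.g. "for hours" gives `"PXH"`).
#'
#' @param count positive integer, or the string `"X"` for vague periods
#' @param unit one of `r paste0('"', PERIOD_UNITS, '"', collapse = ", ")`
#' @param clock whether to render the `T` clock marker; defaults to `TRUE`
#'   for `"MIN"`/`"S"`
#' @export
period_value <- function(count, unit, clock = unit %in% c("MIN", "S")) {
  unit <- match.arg(unit, PERIOD_UNITS)
  vague <- identical(count, "X")
  if (!vague) {
    if (!is_count(count) || count <= 0) stop("period_value: count must be a positive integer or \"X\"")
    count <- as.integer(count)
  }
  if (unit %in% c("MIN", "S") && !clock)
    stop("period_value: ", unit, " requires the clock marker")
  if (unit %in% c("Y", "M", "W") && clock)
    stop("period_value: clock marker invalid for unit ", unit)
  new_value("period", list(count = count, unit = unit, clock = isTRUE(clock)))
}

#' Construct a bounded interval (open-ended duration)
#'
#' "Since"/"until" durations: a bound (`"SIN"` or `"UNT"`) plus an anchor.
#' The anchor is usually a calendar value (`"SIN2007"`); life-stage
#' references ("since his teens" giving `"SINTEENS_REF"`) and past-age
#' values ("since age 3 months" giving `"SINA3M"`) are also accepted as a
#' documented extension.
#'
#' @param bound `"SIN"` or `"UNT"`
#' @param anchor a calendar, categorical or past-age `psytimex_value`
#' @export
bounded_interval <- function(bound, anchor) {
  bound <- match.arg(bound, c("SIN", "UNT"))
  stopifnot(inherits(anchor, "psytimex_value"))
  if (!anchor$kind %in% c("calendar", "categorical", "age"))
    stop("bounded_interval: unsupported anchor kind ", anchor$kind)
  if (anchor$kind == "age" && anchor$mode != "PAST")
    stop("bounded_interval: age anchors must be past-age values")
  new_value("bounded", list(bound = bound, anchor = anchor))
}

#' Construct a range value
#'
#' An explicit start--end duration, rendered with the brackets notation
#' `"(2009, 2012)"`. When both endpoints are fully comparable the start
#' must not be after the end.
#'
#' @param start,end calendar values
#' @export
range_value <- function(start, end) {
  stopifnot(inherits(start, "psytimex_value"), start$kind == "calendar",
            inherits(end, "psytimex_value"), end$kind == "calendar")
  ks <- calendar_key(start); ke <- calendar_key(end)
  if (!is.null(ks) && !is.null(ke) && ks > ke)
    stop("range_value: start is after end")
  new_value("range", list(start = start, end = end))
}

# comparable sort key at common granularity; NULL when date unknown
calendar_key <- function(v) {
  if (!v$date_known) return(NULL)
  sprintf("%04d-%02d-%02d", v$year,
          if (is.null(v$month)) 1L else v$month,
          if (is.null(v$day)) 1L else v$day)
}

#' Construct an age value
#'
#' Age-anchored values: the patient's current age (`mode = "CURRENT"`,
#' rendered `"P45Y"`) or an age in the past (`mode = "PAST"`, rendered
#' `"A15Y"`). Months (`unit = "M"`) are supported for infant ages
#' ("age 3 months" gives `"A3M"`).
#'
#' @param mode `"CURRENT"` or `"PAST"`
#' @param count non-negative integer age
#' @param unit `"Y"` (years, default) or `"M"` (months)
#' @export
age_value <- function(mode, count, unit = "Y") {
  mode <- match.arg(mode, c("CURRENT", "PAST"))
  unit <- match.arg(unit, c("Y", "M"))
  if (!is_count(count) || count < 0) stop("age_value: count must be a non-negative integer")
  new_value("age", list(mode = mode, count = as.integer(count), unit = unit))
}

#' Construct a categorical reference value
#' @param code one of [CATEGORICAL_REFS]
#' @export
categorical_ref <- function(code) {
  code <- match.arg(code, CATEGORICAL_REFS)
  new_value("categorical", list(code = code))
}

#' The UNRESOLVED sentinel value
#' @export
unresolved_value <- function() new_value("unresolved", list())

#' A verbatim foreign value string
#'
#' Used by the TIMEX3 XML reader to preserve values from other annotation
#' schemes that do not parse under the canonical grammar. Serializes to
#' itself; never produced by [parse_value()].
#'
#' @param s the verbatim value string
#' @export
raw_value <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  new_value("raw", list(string = s))
}

#' Serialize a normalized value to its canonical string
#'
#' Total over all variants; month/day/hour/minute are zero-padded to two
#' digits, periods render with the `P` prefix and a `T` before sub-day
#' clock units, ranges render `"(start, end)"`.
#'
#' @param v a `psytimex_value`
#' @return a single string
#' @examples
#' serialize_value(period_value(4, "Y"))            # "P4Y"
#' serialize_value(period_value(15, "MIN"))         # "PT15M"
#' serialize_value(calendar_value(2011, 5))         # "2011-05"
#' serialize_value(range_value(calendar_value(2009), calendar_value(2012)))
#' @export
serialize_value <- function(v) {
  stopifnot(inherits(v, "psytimex_value"))
  switch(v$kind,
    calendar = serialize_calendar(v),
    day_part = v$code,
    period = {
      n <- if (identical(v$count, "X")) "X" else as.character(v$count)
      u <- if (v$unit == "MIN") "M" else v$unit
      paste0("P", if (v$clock) "T" else "", n, u)
    },
    bounded = paste0(v$bound, serialize_value(v$anchor)),
    range = paste0("(", serialize_value(v$start), ", ", serialize_value(v$end), ")"),
    age = paste0(if (v$mode == "CURRENT") "P" else "A", v$count, v$unit),
    categorical = v$code,
    unresolved = "UNRESOLVED",
    raw = v$string,
    stop("serialize_value: unknown kind ", v$kind)
  )
}

serialize_calendar <- function(v) {
  date <- if (v$date_known) {
    s <- sprintf("%04d", v$year)
    if (!is.null(v$month)) s <- paste0(s, sprintf("-%02d", v$month))
    if (!is.null(v$day)) s <- paste0(s, sprintf("-%02d", v$day))
    s
  } else {
    switch(v$granularity, Y = "XXXX", M = "XXXX-XX", D = "XXXX-XX-XX")
  }
  if (!is.null(v$hour)) {
    paste0(date, sprintf("T%02d:%02d", v$hour, v$minute))
  } else {
    date
  }
}

#' Parse a canonical value string
#'
#' Inverse of [serialize_value()]: `parse_value(serialize_value(v))`
#' structurally equals `v` for every variant. `P<n>Y` strings are
#' ambiguous between periods and current-age values; pass the carrying
#' expression's type as `type` to disambiguate (with
#' `type = "AGE_RELATED"` they parse as age values, otherwise as periods).
#'
#' @param s a canonical value string
#' @param type optional expression type used for disambiguation
#' @return a `psytimex_value`
#' @export
parse_value <- function(s, type = NULL) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  s0 <- trimws(s)
  if (s0 == "UNRESOLVED") return(unresolved_value())
  if (s0 %in% CATEGORICAL_REFS) return(categorical_ref(s0))
  if (s0 %in% DAY_PARTS) return(day_part(s0))
  if (grepl("^(SIN|UNT)", s0)) {
    bound <- substr(s0, 1, 3)
    rest <- substr(s0, 4, nchar(s0))
    anchor <- parse_value(rest, type = type)
    return(bounded_interval(bound, anchor))
  }
  if (grepl("^\\(", s0)) {
    m <- regmatches(s0, regexec("^\\(([^,]+), (.+)\\)$", s0))[[1]]
    if (length(m) != 3) stop("parse_value: malformed range: ", s0)
    return(range_value(parse_value(m[2]), parse_value(m[3])))
  }
  # past-age values: unambiguous A prefix
  m <- regmatches(s0, regexec("^A([0-9]+)(Y|M)$", s0))[[1]]
  if (length(m) == 3)
    return(age_value("PAST", as.integer(m[2]), m[3]))
  # P prefix: age (with type hint) or period
  m <- regmatches(s0, regexec("^P([0-9]+)(Y|M)$", s0))[[1]]
  if (length(m) == 3 && identical(type, "AGE_RELATED"))
    return(age_value("CURRENT", as.integer(m[2]), m[3]))
  m <- regmatches(s0, regexec("^P(T?)(X|[0-9]+)(Y|M|W|D|H|S)$", s0))[[1]]
  if (length(m) == 4) {
    clock <- m[2] == "T"
    unit <- m[4]
    if (clock && unit == "M") unit <- "MIN"
    if (clock && unit %in% c("Y", "W"))
      stop("parse_value: clock marker invalid for unit ", unit, " in: ", s0)
    n <- if (m[3] == "X") "X" else as.integer(m[3])
    return(period_value(n, unit, clock = clock))
  }
  v <- parse_calendar(s0)
  if (!is.null(v)) return(v)
  stop("parse_value: unrecognized value string: ", s0)
}

parse_calendar <- function(s) {
  pat <- paste0("^(XXXX|[0-9]{4})",            # year or placeholder
                "(?:-(XX|[0-9]{2})",           # month
                "(?:-(XX|[0-9]{2}))?)?",       # day
                "(?:T([0-9]{2}):([0-9]{2}))?$")
  m <- regmatches(s, regexec(pat, s, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  y <- m[2]; mo <- m[3]; d <- m[4]; h <- m[5]; mi <- m[6]
  unknown <- y == "XXXX"
  if (unknown) {
    if ((mo != "" && mo != "XX") || (d != "" && d != "XX"))
      stop("parse_value: mixed placeholder and literal date parts: ", s)
    gran <- if (d == "XX") "D" else if (mo == "XX") "M" else "Y"
    calendar_value(date_known = FALSE, granularity = gran,
                   hour = if (h == "") NULL else as.integer(h),
                   minute = if (mi == "") NULL else as.integer(mi))
  } else {
    if (mo == "XX" || d == "XX")
      stop("parse_value: mixed placeholder and literal date parts: ", s)
    calendar_value(year = as.integer(y),
                   month = if (mo == "") NULL else as.integer(mo),
                   day = if (d == "") NULL else as.integer(d),
                   hour = if (h == "") NULL else as.integer(h),
                   minute = if (mi == "") NULL else as.integer(mi))
  }
}

#' Test two values for structural equality
#' @param a,b `psytimex_value` objects
#' @export
values_equal <- function(a, b) identical(serialize_value(a), serialize_value(b)) && a$kind == b$kind
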