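# independent oracles and fixture builders shared across tests

# brute-force maximum bipartite matching cardinality by exhaustive
# enumeration (the oracle for lenient_match; feasible for <= 8 spans/side)
bf_max_matching <- function(ov) {
  if (nrow(ov) == 0 || ncol(ov) == 0) return(0L)
  rec <- function(i, used) {
    if (i > nrow(ov)) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(ov[i, ])) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, ncol(ov)))
}

overlap_matrix <- function(A, B) {
  ea <- A$expressions; eb <- B$expressions
  m <- matrix(FALSE, length(ea), length(eb))
  for (i in seq_along(ea)) for (j in seq_along(eb))
    m[i, j] <- ea[[i]]$start < eb[[j]]$end && eb[[j]]$start < ea[[i]]$end
  m
}

# random annotation set over a virtual text of length text_len; spans may
# overlap each other only across sets, not within (annotators mark
# disjoint spans), so spans are laid out left to right
random_ann_set <- function(n, text_len = 80, doc_id = "r") {
  if (n == 0) return(annotation_set(doc_id))
  starts <- sort(sample(0:(text_len - 2), n))
  exprs <- lapply(seq_len(n), function(i) {
    s <- starts[i]
    lim <- if (i < n) starts[i + 1] else text_len
    e <- min(s + sample(1:8, 1), lim, text_len)
    if (e <= s) e <- s + 1
    time_expression(s, e, strrep("x", e - s), sample(TIMEX_TYPES, 1),
                    value = calendar_value(2000 + i))
  })
  annotation_set(doc_id, exprs)
}

# random normalized value plus the type hint needed to re-parse it
random_value <- function() {
  kind <- sample(c("calendar", "day_part", "period", "bounded", "range",
                   "age", "categorical", "unresolved"), 1)
  y <- function() sample(1900:2100, 1)
  cal <- function(time_ok = TRUE) {
    g <- sample(1:3, 1)
    hr <- if (time_ok && stats::runif(1) < 0.3)
      list(hour = sample(0:23, 1), minute = sample(0:59, 1)) else list()
    if (stats::runif(1) < 0.15 && length(hr))
      return(do.call(calendar_value,
                     c(list(date_known = FALSE,
                            granularity = sample(c("Y", "M", "D"), 1)), hr)))
    args <- list(year = y())
    if (g >= 2) args$month <- sample(1:12, 1)
    if (g >= 3) args$day <- sample(1:28, 1)
    do.call(calendar_value, c(args, hr))
  }
  switch(kind,
    calendar = list(v = cal(), type = "DATE"),
    day_part = list(v = day_part(sample(DAY_PARTS, 1)), type = "TIME"),
    period = {
      u <- sample(c("Y", "M", "W", "D", "H", "MIN", "S"), 1)
      n <- if (stats::runif(1) < 0.2) "X" else sample(1:40, 1)
      cl <- if (u %in% c("MIN", "S")) TRUE else
        if (u %in% c("D", "H")) stats::runif(1) < 0.5 else FALSE
      list(v = period_value(n, u, clock = cl), type = "DURATION")
    },
    bounded = {
      anchor <- switch(sample(3, 1),
        cal(time_ok = FALSE),
        categorical_ref(sample(CATEGORICAL_REFS, 1)),
        age_value("PAST", sample(0:80, 1), sample(c("Y", "M"), 1)))
      if (anchor$kind == "calendar" && !anchor$date_known)
        anchor <- calendar_value(y())
      list(v = bounded_interval(sample(c("SIN", "UNT"), 1), anchor),
           type = "DURATION")
    },
    range = {
      a <- y(); b <- a + sample.int(2101 - a, 1) - 1L
      list(v = range_value(calendar_value(a), calendar_value(b)),
           type = "DURATION")
    },
    age = list(v = age_value(sample(c("CURRENT", "PAST"), 1),
                             sample(0:90, 1), sample(c("Y", "M"), 1)),
               type = "AGE_RELATED"),
    categorical = list(v = categorical_ref(sample(CATEGORICAL_REFS, 1)),
                       type = "DATE"),
    unresolved = list(v = unresolved_value(), type = "DATE"))
}

# one-line normalization for tests: surface + type (+ optional dct)
norm1 <- function(surface, type, dct = "2011-03-14", date_order = "DMY") {
  ctx <- anchor_context(dct = dct, date_order = date_order)
  tx <- time_expression(0, nchar(surface), surface, type)
  serialize_value(normalize_timex(tx, ctx)$value)
}
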