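spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Kuhn's augmenting-path maximum bipartite matching over the overlap
# relation; iterating A and B in start order makes ties resolve to the
# leftmost pairing deterministically
max_matching <- function(adj, n_b) {
  match_b <- rep(NA_integer_, n_b)   # b index -> a index
  try_augment <- function(a, seen) {
    for (b in adj[[a]]) {
      if (seen[b]) next
      seen[b] <- TRUE
      if (is.na(match_b[b]) || try_augment(match_b[b], seen)) {
        match_b[b] <<- a
        return(TRUE)
      }
    }
    FALSE
  }
  for (a in seq_along(adj)) try_augment(a, rep(FALSE, n_b))
  match_b
}

#' Lenient span matching between two annotation sets
#'
#' A true positive is a span identified in both sets, allowing any
#' character overlap. Multiple-overlap conflicts are resolved by exact
#' maximum-cardinality one-to-one matching (sets are small), with ties
#' broken toward the leftmost pairing.
#'
#' @param A,B `psytimex_annotations` for the same document (system or
#'   annotator 1 in `A`, reference or annotator 2 in `B`)
#' @return an object of class `psytimex_matchset`: `pairs` (data frame of
#'   matched index pairs `a`, `b`), `unmatched_a`, `unmatched_b`, and the
#'   two input sets
#' @export
lenient_match <- function(A, B) {
  stopifnot(inherits(A, "psytimex_annotations"),
            inherits(B, "psytimex_annotations"))
  if (!identical(A$doc_id, B$doc_id))
    stop("lenient_match: annotation sets reference different documents: ",
         A$doc_id, " vs ", B$doc_id)
  ea <- A$expressions; eb <- B$expressions
  sb <- vapply(eb, `[[`, integer(1), "start")
  nb <- vapply(eb, `[[`, integer(1), "end")
  adj <- lapply(ea, function(a)
    which(spans_overlap(a$start, a$end, sb, nb)))
  mb <- max_matching(adj, length(eb))
  pairs <- data.frame(a = mb[!is.na(mb)], b = which(!is.na(mb)))
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_along(ea), pairs$a),
                 unmatched_b = setdiff(seq_along(eb), pairs$b),
                 A = A, B = B),
            class = "psytimex_matchset")
}

#' @export
print.psytimex_matchset <- function(x, ...) {
  cat(sprintf("<matchset %s: %d matches, %d unmatched A, %d unmatched B>\n",
              x$A$doc_id, nrow(x$pairs), length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}

#' Lenient precision, recall and F1
#'
#' Precision is matches over `|A|`, recall matches over `|B|`, F1 their
#' harmonic mean. Degenerate conventions (the reference corpus never
#' needs them): both sets empty gives (1, 1, 1); an empty `A` against a
#' non-empty `B` gives precision 1 by convention, recall 0, F1 0 (and
#' symmetrically for an empty `B`).
#'
#' @param A,B annotation sets, or a precomputed `psytimex_matchset` in
#'   `A` (then `B` is ignored)
#' @return named numeric vector `c(precision =, recall =, f1 =)`
#' @export
lenient_f1 <- function(A, B = NULL) {
  m <- if (inherits(A, "psytimex_matchset")) A else lenient_match(A, B)
  na <- length(m$A$expressions); nb <- length(m$B$expressions)
  nm <- nrow(m$pairs)
  p <- if (na == 0) 1 else nm / na
  r <- if (nb == 0) 1 else nm / nb
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

match_values <- function(m) {
  val <- function(e) if (is.null(e$value)) NA_character_ else
    serialize_value(e$value)
  data.frame(
    va = vapply(m$A$expressions[m$pairs$a], val, character(1)),
    vb = vapply(m$B$expressions[m$pairs$b], val, character(1)),
    ta = vapply(m$A$expressions[m$pairs$a], `[[`, character(1), "type"),
    tb = vapply(m$B$expressions[m$pairs$b], `[[`, character(1), "type"),
    stringsAsFactors = FALSE)
}

#' Normalization value accuracy on matched spans
#'
#' The proportion of matched pairs whose canonical value strings are
#' identical. Computed only over matches; an empty match set has no
#' defined accuracy and returns `NA` (never 0).
#'
#' @param m a `psytimex_matchset` whose expressions carry values
#' @return a fraction in `[0, 1]`, or `NA` for an empty match set
#' @export
value_accuracy <- function(m) {
  stopifnot(inherits(m, "psytimex_matchset"))
  if (nrow(m$pairs) == 0) return(NA_real_)
  mv <- match_values(m)
  mean(mv$va == mv$vb)
}

# relaxed comparison: Time-typed pairs with full date-time values are
# compared on the "Thh:mm" clock portion only
DATETIME_RE <- "^(?:[0-9]{4}-[0-9]{2}-[0-9]{2}|XXXX-XX-XX)(T[0-9]{2}:[0-9]{2})$"

relaxed_equal <- function(va, vb, ref_type) {
  if (va == vb) return(TRUE)
  if (!identical(ref_type, "TIME")) return(FALSE)
  ma <- regmatches(va, regexec(DATETIME_RE, va))[[1]]
  mb <- regmatches(vb, regexec(DATETIME_RE, vb))[[1]]
  length(ma) == 2 && length(mb) == 2 && ma[2] == mb[2]
}

#' Relaxed value accuracy (acc*)
#'
#' As [value_accuracy()], but pairs whose reference type is `TIME` and
#' whose values are full date-times (`"YYYY-MM-DDThh:mm"` or the
#' placeholder-date form) are compared only on the `"Thh:mm"` clock
#' portion -- so `"2011-03-14T18:00"` and `"2011-03-13T18:00"` count as a
#' match (both `T18:00`). All other pairs are compared exactly, hence
#' acc* >= acc always.
#'
#' @inheritParams value_accuracy
#' @export
relaxed_time_accuracy <- function(m) {
  stopifnot(inherits(m, "psytimex_matchset"))
  if (nrow(m$pairs) == 0) return(NA_real_)
  mv <- match_values(m)
  mean(mapply(relaxed_equal, mv$va, mv$vb, mv$tb))
}

#' Per-type evaluation table
#'
#' Match counts, value accuracy and relaxed accuracy for each of the five
#' expression types. A pair's type is taken from the reference side (`B`);
#' pairs where the two sides disagree on the type are counted under the
#' reference type, with the disagreement tallied.
#'
#' @inheritParams value_accuracy
#' @return a data frame with one row per type: `type`, `n_matches`,
#'   `acc`, `acc_star`, `type_disagreements`
#' @export
per_type_report <- function(m) {
  stopifnot(inherits(m, "psytimex_matchset"))
  mv <- match_values(m)
  rows <- lapply(TIMEX_TYPES, function(tt) {
    sel <- mv$tb == tt
    k <- sum(sel)
    data.frame(
      type = tt, n_matches = k,
      acc = if (k == 0) NA_real_ else mean(mv$va[sel] == mv$vb[sel]),
      acc_star = if (k == 0) NA_real_ else
        mean(mapply(relaxed_equal, mv$va[sel], mv$vb[sel], mv$tb[sel])),
      type_disagreements = sum(sel & mv$ta != mv$tb),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Bundles lenient P/R/F1, value accuracy, relaxed accuracy and the
#' per-type table for a pair of annotation sets (or lists of sets, pooled
#' micro-average across documents; `macro = TRUE` averages the per-document
#' metrics instead).
#'
#' @param A,B annotation sets or parallel lists of annotation sets
#'   (matched by `doc_id`)
#' @param macro macro-average across documents instead of pooling
#' @return an object of class `psytimex_eval`: `precision`, `recall`,
#'   `f1`, `n_matches`, `acc`, `acc_star`, `per_type`
#' @export
evaluate_annotations <- function(A, B, macro = FALSE) {
  if (inherits(A, "psytimex_annotations")) A <- list(A)
  if (inherits(B, "psytimex_annotations")) B <- list(B)
  ids_a <- vapply(A, `[[`, character(1), "doc_id")
  ids_b <- vapply(B, `[[`, character(1), "doc_id")
  if (!setequal(ids_a, ids_b))
    stop("evaluate_annotations: document sets differ")
  B <- B[match(ids_a, ids_b)]
  ms <- mapply(lenient_match, A, B, SIMPLIFY = FALSE)
  if (macro) {
    prf <- rowMeans(vapply(ms, lenient_f1, numeric(3)))
    accs <- vapply(ms, value_accuracy, numeric(1))
    accr <- vapply(ms, relaxed_time_accuracy, numeric(1))
    out <- list(precision = prf[["precision"]], recall = prf[["recall"]],
                f1 = prf[["f1"]],
                n_matches = sum(vapply(ms, function(m) nrow(m$pairs),
                                       integer(1))),
                acc = mean(accs, na.rm = TRUE),
                acc_star = mean(accr, na.rm = TRUE))
  } else {
    nm <- sum(vapply(ms, function(m) nrow(m$pairs), integer(1)))
    na <- sum(vapply(ms, function(m) length(m$A$expressions), integer(1)))
    nb <- sum(vapply(ms, function(m) length(m$B$expressions), integer(1)))
    p <- if (na == 0) 1 else nm / na
    r <- if (nb == 0) 1 else nm / nb
    mv <- do.call(rbind, lapply(ms, match_values))
    out <- list(precision = p, recall = r,
                f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
                n_matches = nm,
                acc = if (nm == 0) NA_real_ else mean(mv$va == mv$vb),
                acc_star = if (nm == 0) NA_real_ else
                  mean(mapply(relaxed_equal, mv$va, mv$vb, mv$tb)))
  }
  per_type <- lapply(ms, per_type_report)
  agg <- Reduce(function(x, y) {
    k <- x$n_matches + y$n_matches
    wmean <- function(a, b) ifelse(k == 0, NA_real_,
      (ifelse(is.na(a), 0, a) * x$n_matches +
       ifelse(is.na(b), 0, b) * y$n_matches) / pmax(k, 1))
    data.frame(type = x$type, n_matches = k,
               acc = wmean(x$acc, y$acc),
               acc_star = wmean(x$acc_star, y$acc_star),
               type_disagreements = x$type_disagreements + y$type_disagreements,
               stringsAsFactors = FALSE)
  }, per_type)
  out$per_type <- agg
  structure(out, class = "psytimex_eval")
}

#' @export
print.psytimex_eval <- function(x, ...) {
  cat(sprintf("lenient P %.3f / R %.3f / F1 %.3f  (%d matches)\n",
              x$precision, x$recall, x$f1, x$n_matches))
  cat(sprintf("value accuracy %.3f, relaxed (clock-only Time) %.3f\n",
              x$acc, x$acc_star))
  print(x$per_type, row.names = FALSE)
  invisible(x)
}
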