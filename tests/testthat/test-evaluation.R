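mkann <- function(spans, types = NULL, values = NULL, doc_id = "d") {
  exprs <- lapply(seq_along(spans), function(i) {
    sp <- spans[[i]]
    time_expression(sp[1], sp[2], strrep("x", sp[2] - sp[1]),
                    if (is.null(types)) "DATE" else types[i],
                    value = if (is.null(values)) NULL else
                      parse_value(values[i], type = if (is.null(types))
                        "DATE" else types[i]))
  })
  annotation_set(doc_id, exprs)
}

test_that("lenient matching counts any-overlap spans once each", {
  A <- mkann(list(c(0, 5), c(10, 15), c(20, 25)))
  m <- lenient_match(A, A)
  expect_identical(nrow(m$pairs), 3L)
  expect_length(m$unmatched_a, 0)
  expect_length(m$unmatched_b, 0)

  m <- lenient_match(mkann(list(c(0, 5))), mkann(list(c(3, 8))))
  expect_identical(nrow(m$pairs), 1L)

  expect_error(lenient_match(mkann(list(c(0, 5))),
                             mkann(list(c(0, 5)), doc_id = "other")),
               "different documents")
})

test_that("matching cardinality equals the brute-force maximum", {
  set.seed(41)
  for (i in 1:300) {
    A <- random_ann_set(sample(0:8, 1), doc_id = "r")
    B <- random_ann_set(sample(0:8, 1), doc_id = "r")
    m <- lenient_match(A, B)
    expect_identical(nrow(m$pairs), bf_max_matching(overlap_matrix(A, B)),
                     label = sprintf("instance %d", i))
    # one-to-one and overlapping
    expect_identical(anyDuplicated(m$pairs$a), 0L)
    expect_identical(anyDuplicated(m$pairs$b), 0L)
    for (k in seq_len(nrow(m$pairs))) {
      ea <- A$expressions[[m$pairs$a[k]]]
      eb <- B$expressions[[m$pairs$b[k]]]
      expect_true(ea$start < eb$end && eb$start < ea$end)
    }
  }
})

test_that("lenient F1 handles the worked and degenerate cases", {
  A <- mkann(list(c(0, 5), c(10, 15)))
  expect_equal(lenient_f1(A, A), c(precision = 1, recall = 1, f1 = 1))
  # |A| = 2, |B| = 1, one match
  B <- mkann(list(c(0, 5)))
  expect_equal(lenient_f1(A, B),
               c(precision = 0.5, recall = 1, f1 = 2 / 3))
  # empty conventions
  E <- mkann(list())
  expect_equal(lenient_f1(E, E), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(lenient_f1(E, B), c(precision = 1, recall = 0, f1 = 0))
  expect_equal(lenient_f1(B, E), c(precision = 0, recall = 1, f1 = 0))
})

test_that("F1 is symmetric with precision and recall exchanged", {
  set.seed(43)
  for (i in 1:40) {
    A <- random_ann_set(sample(0:8, 1))
    B <- random_ann_set(sample(0:8, 1), doc_id = "r")
    A$doc_id <- "r"
    f_ab <- lenient_f1(A, B)
    f_ba <- lenient_f1(B, A)
    expect_equal(f_ab[["precision"]], f_ba[["recall"]])
    expect_equal(f_ab[["recall"]], f_ba[["precision"]])
    expect_equal(f_ab[["f1"]], f_ba[["f1"]])
  }
})

test_that("value accuracy is the share of identical canonical values", {
  spans <- list(c(0, 5), c(10, 15), c(20, 25), c(30, 35))
  A <- mkann(spans, values = c("2011-05", "P4Y", "SIN2007", "2009"))
  B <- mkann(spans, values = c("2011-05", "P4Y", "SIN2007", "2009"))
  expect_equal(value_accuracy(lenient_match(A, B)), 1)
  B <- mkann(spans, values = c("2011-05", "P4Y", "SIN2007", "2010"))
  expect_equal(value_accuracy(lenient_match(A, B)), 0.75)
  # date-part mismatch in a full date-time is a raw mismatch
  A <- mkann(list(c(0, 5)), types = "TIME", values = "2011-03-14T18:00")
  B <- mkann(list(c(0, 5)), types = "TIME", values = "2011-03-13T18:00")
  expect_equal(value_accuracy(lenient_match(A, B)), 0)
  # empty match set: explicitly undefined
  expect_true(is.na(value_accuracy(lenient_match(mkann(list()),
                                                 mkann(list())))))
})

test_that("relaxed accuracy compares Time values on the clock part only", {
  A <- mkann(list(c(0, 5)), types = "TIME", values = "2011-03-14T18:00")
  B <- mkann(list(c(0, 5)), types = "TIME", values = "2011-03-13T18:00")
  m <- lenient_match(A, B)
  expect_equal(value_accuracy(m), 0)
  expect_equal(relaxed_time_accuracy(m), 1)
  # placeholder dates relax too
  A <- mkann(list(c(0, 5)), types = "TIME", values = "XXXX-XX-XXT18:00")
  expect_equal(relaxed_time_accuracy(lenient_match(A, B)), 1)
  # different clocks stay mismatched
  B2 <- mkann(list(c(0, 5)), types = "TIME", values = "2011-03-13T19:00")
  expect_equal(relaxed_time_accuracy(lenient_match(A, B2)), 0)
  # Date pairs differing in day get no relaxation
  A <- mkann(list(c(0, 5)), types = "DATE", values = "2011-03-14T18:00")
  B <- mkann(list(c(0, 5)), types = "DATE", values = "2011-03-13T18:00")
  expect_equal(relaxed_time_accuracy(lenient_match(A, B)), 0)
})

test_that("acc* >= acc on random valued instances", {
  set.seed(47)
  vals <- c("2011-03-14T18:00", "2011-03-13T18:00", "XXXX-XX-XXT18:00",
            "2011-03-14T19:00", "P4Y", "SIN2007", "TMO")
  for (i in 1:60) {
    n <- sample(1:8, 1)
    spans <- lapply(seq_len(n), function(k) c(10 * k, 10 * k + 5))
    ty <- sample(c("TIME", "DATE", "DURATION"), n, replace = TRUE)
    A <- mkann(spans, types = ty, values = sample(vals, n, replace = TRUE))
    B <- mkann(spans, types = ty, values = sample(vals, n, replace = TRUE))
    m <- lenient_match(A, B)
    expect_gte(relaxed_time_accuracy(m), value_accuracy(m))
  }
})

test_that("per-type rows conserve matches and follow the reference type", {
  spans <- lapply(1:10, function(k) c(10 * k, 10 * k + 5))
  ta <- c(rep("DATE", 4), rep("TIME", 3), "DURATION", "FREQUENCY",
          "AGE_RELATED")
  tb <- ta; tb[4] <- "DURATION"   # one type disagreement
  va <- c("2011", "2012", "2013", "2014", "2011-03-14T18:00",
          "2011-03-13T18:00", "TMO", "P4Y", "P1W", "A15Y")
  vb <- c("2011", "2012", "1999", "2014", "2011-03-10T18:00",
          "2011-03-13T18:00", "TNI", "P4Y", "P1W", "P15Y")
  A <- mkann(spans, types = ta, values = va)
  B <- mkann(spans, types = tb, values = vb)
  m <- lenient_match(A, B)
  rep_ <- per_type_report(m)
  expect_identical(sum(rep_$n_matches), nrow(m$pairs))
  expect_identical(rep_$type, TIMEX_TYPES)
  # hand-computed rows: DATE ref side has spans 1,2,3 (2 of 3 equal);
  # span 4 counts under DURATION (ref type) as a disagreement
  expect_identical(rep_$n_matches, c(3L, 3L, 2L, 1L, 1L))
  expect_equal(rep_$acc[rep_$type == "DATE"], 2 / 3)
  # TIME ref pairs 5,6,7: only pair 6 agrees raw; relaxation adds pair 5
  # (same clock, different date) but not the TMO/TNI day-part pair
  expect_equal(rep_$acc[rep_$type == "TIME"], 1 / 3)
  expect_equal(rep_$acc_star[rep_$type == "TIME"], 2 / 3)
  expect_identical(rep_$type_disagreements[rep_$type == "DURATION"], 1L)
  expect_equal(rep_$acc[rep_$type == "AGE_RELATED"], 0)
})

test_that("evaluate_annotations pools across documents (micro) and macros", {
  A1 <- mkann(list(c(0, 5), c(10, 15)), doc_id = "d1",
              values = c("2011", "2012"))
  B1 <- mkann(list(c(0, 5), c(10, 15)), doc_id = "d1",
              values = c("2011", "1999"))
  A2 <- mkann(list(c(0, 5)), doc_id = "d2", values = "P4Y")
  B2 <- mkann(list(c(0, 5)), doc_id = "d2", values = "P4Y")
  ev <- evaluate_annotations(list(A1, A2), list(B1, B2))
  expect_equal(ev$f1, 1)
  expect_equal(ev$acc, 2 / 3)          # pooled: 2 of 3 values agree
  ev_m <- evaluate_annotations(list(A1, A2), list(B1, B2), macro = TRUE)
  expect_equal(ev_m$acc, mean(c(0.5, 1)))
})
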