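# the printed surface -> value oracle table must reproduce exactly
ORACLE_TABLE <- list(
  list("for 4 years", "DURATION", "P4Y"),
  list("for 15 min", "DURATION", "PT15M"),
  list("since 2007", "DURATION", "SIN2007"),
  list("2009–2012", "DURATION", "(2009, 2012)"),
  list("for hours", "DURATION", "PXH"),
  list("a 45 year old", "AGE_RELATED", "P45Y"),
  list("when he was 15", "AGE_RELATED", "A15Y"),
  list("when he was a child", "AGE_RELATED", "CHILD_REF"),
  list("in the past", "DATE", "PAST_REF"),
  list("now", "DATE", "PRESENT_REF"),
  list("in the morning", "TIME", "TMO"),
  list("at night", "TIME", "TNI"),
  list("6 pm sharp", "TIME", "2011-03-14T18:00"),
  list("oct 2009", "DATE", "2009-10"),
  list("at age 8", "AGE_RELATED", "A8Y"),
  list("when he was 8 years old", "AGE_RELATED", "A8Y"),
  list("in his teens", "AGE_RELATED", "TEENS_REF"),
  list("since his teens", "AGE_RELATED", "SINTEENS_REF"),
  list("today", "DATE", "2011-03-14"),
  list("2 yrs back", "DATE", "2009"))

test_that("the normalization oracle table reproduces exactly", {
  for (cs in ORACLE_TABLE) {
    expect_identical(norm1(cs[[1]], cs[[2]]), cs[[3]],
                     label = sprintf("normalize(\"%s\")", cs[[1]]))
  }
  # bound wrapping of a relative anchor
  expect_identical(norm1("until a year ago", "DURATION", dct = "2019-06-01"),
                   "UNT2018")
  # bounded age extension
  expect_identical(norm1("since age 3 months", "AGE_RELATED"), "SINA3M")
})

test_that("relative resolution follows the anchor at the right granularity", {
  ctx <- anchor_context(dct = "2011-03-14")
  expect_identical(serialize_value(resolve_relative("today", ctx)),
                   "2011-03-14")
  expect_identical(serialize_value(resolve_relative("2 yrs back", ctx)),
                   "2009")
  expect_identical(serialize_value(resolve_relative("3 months ago", ctx)),
                   "2010-12")
  expect_identical(serialize_value(resolve_relative("2 weeks ago", ctx)),
                   "2011-02-28")
  expect_identical(serialize_value(resolve_relative("yesterday", ctx)),
                   "2011-03-13")
  # "last week" resolves to the Monday of the preceding ISO week
  # (2011-03-14 is itself a Monday)
  expect_identical(serialize_value(resolve_relative("last week", ctx)),
                   "2011-03-07")
  expect_identical(serialize_value(resolve_relative("last year", ctx)), "2010")
  # no anchor: placeholders at matching granularity, never invented dates
  noctx <- anchor_context()
  expect_identical(serialize_value(resolve_relative("2 yrs back", noctx)),
                   "XXXX")
  expect_identical(serialize_value(resolve_relative("3 months ago", noctx)),
                   "XXXX-XX")
  expect_identical(serialize_value(resolve_relative("yesterday", noctx)),
                   "XXXX-XX-XX")
})

test_that("granularity is never finer than surface plus anchor", {
  # year-granular relatives yield bare years even with a full-date anchor
  expect_match(norm1("4 years ago", "DATE"), "^[0-9]{4}$")
  expect_match(norm1("5 months ago", "DATE"), "^[0-9]{4}-[0-9]{2}$")
  expect_match(norm1("May 2011", "DATE"), "^2011-05$")
  expect_match(norm1("2007", "DATE"), "^2007$")
})

test_that("shifting the DCT shifts all day-granular anchored values equally", {
  surfaces <- c("today", "yesterday", "3 days ago", "2 weeks ago", "tomorrow")
  d1 <- as.Date("2011-03-14")
  for (k in c(1, 30, 365)) {
    v1 <- vapply(surfaces, norm1, character(1), type = "DATE", dct = d1)
    v2 <- vapply(surfaces, norm1, character(1), type = "DATE", dct = d1 + k)
    expect_identical(as.integer(as.Date(v2) - as.Date(v1)),
                     rep(as.integer(k), length(surfaces)))
  }
})

test_that("deictic present stays PRESENT_REF; only explicit today is the DCT", {
  expect_identical(norm1("currently", "DATE"), "PRESENT_REF")
  expect_identical(norm1("at this time", "DATE"), "PRESENT_REF")
  expect_identical(norm1("today", "DATE"), "2011-03-14")
})

test_that("times inherit the date from the anchor, else placeholders", {
  expect_identical(norm1("at 9 pm", "TIME"), "2011-03-14T21:00")
  expect_identical(norm1("at 9 pm", "TIME", dct = NULL), "XXXX-XX-XXT21:00")
  expect_identical(norm1("at 21:30", "TIME"), "2011-03-14T21:30")
  expect_identical(norm1("12 am", "TIME"), "2011-03-14T00:00")
})

test_that("numeric date order is configurable (DMY default, MDY switch)", {
  expect_identical(norm1("03/05/1966", "DATE"), "1966-05-03")
  expect_identical(norm1("03/05/1966", "DATE", date_order = "MDY"),
                   "1966-03-05")
  expect_identical(norm1("1966/05/03", "DATE"), "1966-05-03")
})

test_that("unknown surfaces get the UNRESOLVED sentinel, never dropped", {
  out <- normalize_timex(
    time_expression(0, 13, "week thirteen", "DATE"),
    anchor_context(dct = "2011-03-14"))
  expect_identical(serialize_value(out$value), "UNRESOLVED")
})

test_that("frequencies use the period template with a count attribute", {
  ctx <- anchor_context()
  tx <- normalize_timex(time_expression(0, 12, "twice a week", "FREQUENCY"), ctx)
  expect_identical(serialize_value(tx$value), "P1W")
  expect_identical(tx$meta$freq_count, 2L)
  expect_identical(norm1("daily", "FREQUENCY"), "P1D")
  tx <- normalize_timex(time_expression(0, 13, "3 times a day", "FREQUENCY"), ctx)
  expect_identical(serialize_value(tx$value), "P1D")
  expect_identical(tx$meta$freq_count, 3L)
})

test_that("age lexicon drives categorical normalization and is replaceable", {
  tx <- time_expression(0, 16, "during childhood", "AGE_RELATED")
  expect_identical(serialize_value(postprocess_age(tx)$value), "CHILD_REF")
  # custom lexicon
  lex <- c("childhood" = "SCHOOL_REF")
  expect_identical(serialize_value(postprocess_age(tx, lex)$value),
                   "SCHOOL_REF")
  # non-categorical targets rejected
  expect_error(postprocess_age(tx, c(childhood = "P4Y")), "non-categorical")
  # fallthrough is OTHER_REF
  tx <- time_expression(0, 19, "when he was younger", "AGE_RELATED")
  expect_identical(serialize_value(postprocess_age(tx)$value), "OTHER_REF")
})

test_that("life-stage references map to configurable past-age ranges", {
  r <- age_ref_to_range("TEENS_REF")
  expect_identical(serialize_value(r$start), "A13Y")
  expect_identical(serialize_value(r$end), "A19Y")
  r <- age_ref_to_range("CHILD_REF")
  expect_identical(serialize_value(r$start), "A0Y")
  expect_identical(serialize_value(r$end), "A12Y")
  expect_null(age_ref_to_range("OTHER_REF"))
  # user-overridable
  r <- age_ref_to_range("CHILD_REF", list(CHILD_REF = c(2L, 10L)))
  expect_identical(serialize_value(r$start), "A2Y")
})

test_that("normalization is deterministic given (doc, DCT, rules, lexicon)", {
  corp <- generate_corpus(gen_profile(n_docs = 3, seed = 5,
                                      mean_tokens = 300))
  for (doc in corp$docs) {
    a1 <- tag_document(doc)
    a2 <- tag_document(doc)
    expect_identical(as.data.frame(a1), as.data.frame(a2))
  }
})

test_that("the DCT policy can re-anchor from the first in-text date", {
  txt <- paste0("Letter dated 5 October 2012.\n\nSeen today for review, ",
                "next appointment tomorrow.")
  doc <- document("d", txt, dct = "2013-01-01")
  a_struct <- as.data.frame(tag_document(doc, dct_policy = "STRUCTURED"))
  a_text <- as.data.frame(tag_document(doc, dct_policy = "FIRST_IN_TEXT_DATE"))
  expect_identical(a_struct$value[a_struct$surface == "today"], "2013-01-01")
  expect_identical(a_text$value[a_text$surface == "today"], "2012-10-05")
  a_ovr <- as.data.frame(tag_document(doc, dct_policy = "OVERRIDE",
                                      override = "2000-06-15"))
  expect_identical(a_ovr$value[a_ovr$surface == "today"], "2000-06-15")
})
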