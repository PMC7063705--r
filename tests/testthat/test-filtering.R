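mkdoc <- function(text, id = "d", patient = NULL) {
  document(id, text, meta = if (is.null(patient)) list() else
    list(patient_id = patient))
}

test_that("doc_stats computes length and mean line length", {
  expect_equal(doc_stats(mkdoc("abc\ndefgh")),
               c(char_length = 9, avg_line_length = 4))
  long <- strrep("x", 2000)
  expect_equal(doc_stats(mkdoc(long)),
               c(char_length = 2000, avg_line_length = 2000))
  expect_equal(doc_stats(mkdoc("")), c(char_length = 0, avg_line_length = 0))
  # trailing newline does not add an empty line
  expect_equal(doc_stats(mkdoc("ab\ncd\n"))[["avg_line_length"]], 2)
  # 50-line generated fixture vs brute-force recount
  set.seed(3)
  lines <- vapply(1:50, function(i)
    strrep("a", sample(1:120, 1)), character(1))
  txt <- paste(lines, collapse = "\n")
  st <- doc_stats(mkdoc(txt))
  expect_equal(st[["char_length"]], nchar(txt))
  expect_equal(st[["avg_line_length"]], mean(nchar(lines)))
})

test_that("keyword counting is whole-word and case-insensitive", {
  kw <- c("hallucinations", "delusions")
  expect_identical(keyword_count(mkdoc("auditory hallucinations and delusions"),
                                 kw), 2L)
  expect_identical(keyword_count(mkdoc("Hallucinations"), kw), 1L)
  expect_identical(keyword_count(mkdoc("hallucinationsX"), kw), 0L)
  expect_identical(keyword_count(mkdoc("hallucinationsX"), kw,
                                 substring = TRUE), 1L)
  # occurrences, not presence: repeated terms count each time
  expect_identical(keyword_count(mkdoc("delusions, delusions"), kw), 2L)
  # multi-word terms match across whitespace
  expect_identical(keyword_count(mkdoc("reports hearing  voices at night"),
                                 "hearing voices"), 1L)
  expect_length(psychosis_keywords(), 26L)
})

test_that("percentile thresholds use the nearest-rank method", {
  corp <- lapply(c(10, 20, 30, 40), function(n) mkdoc(strrep("x", n)))
  thr <- derive_percentile_thresholds(corp)
  expect_equal(thr[["min_chars"]], 20)
  one <- mkdoc("abcde")
  thr <- derive_percentile_thresholds(list(one))
  expect_equal(thr[["min_chars"]], 5)
  expect_equal(thr[["min_avg_line"]], 5)
  # constructed corpus with median length exactly 2000
  lens <- c(500, 1200, 2000, 3100, 4000)
  corp <- lapply(lens, function(n) mkdoc(strrep("x", n)))
  expect_equal(derive_percentile_thresholds(corp)[["min_chars"]], 2000)
  expect_error(derive_percentile_thresholds(list()), "empty")
})

# a document with controllable stats: n chars total, one keyword if asked,
# k timex mentions ("5 October 2012" repeated), long single line
ctrl_doc <- function(id, chars, kw = TRUE, timexes = 10, patient = "p1",
                     avg_line = NULL) {
  body <- paste(c(if (kw) "hallucinations",
                  rep("on 5 October 2012 seen", timexes)), collapse = " ")
  pad <- max(0, chars - nchar(body))
  text <- paste0(body, strrep("z", pad))
  text <- substr(text, 1, max(chars, nchar(body)))
  if (!is.null(avg_line)) {
    # re-wrap into fixed-width lines
    n <- nchar(text)
    starts <- seq(1, n, by = avg_line)
    text <- paste(substring(text, starts, pmin(starts + avg_line - 1, n)),
                  collapse = "\n")
  }
  mkdoc(text, id, patient)
}

test_that("filter stages use the stated strict/inclusive semantics", {
  cfg <- filter_config()
  # short doc excluded at length stage despite keywords and timexes
  short <- ctrl_doc("s", 1500, kw = TRUE, timexes = 10)
  res <- filter_corpus(list(short), cfg)
  expect_length(res$retained, 0)
  expect_false(res$docs$pass_length)
  # 2500 chars, long lines, 1 keyword, 6 timexes is retained
  good <- ctrl_doc("g", 2500, kw = TRUE, timexes = 6)
  res <- filter_corpus(list(good), cfg)
  expect_length(res$retained, 1)
  # exactly 2000 characters is excluded (strictly greater than)
  expect_identical(nchar(ctrl_doc("b", 2000)$text), 2000L)
  res <- filter_corpus(list(ctrl_doc("b", 2000)), cfg)
  expect_length(res$retained, 0)
  # exactly 5 time expressions is excluded (strictly more than 5)
  five <- ctrl_doc("f", 2500, kw = TRUE, timexes = 5)
  expect_identical(count_timexes(five), 5L)
  res <- filter_corpus(list(five), cfg)
  expect_length(res$retained, 0)
  expect_false(res$docs$pass_timex)
  # average line length boundary is strict too
  wrapped <- ctrl_doc("w", 2500, kw = TRUE, timexes = 6, avg_line = 30)
  expect_lte(doc_stats(wrapped)[["avg_line_length"]], 30)
  res <- filter_corpus(list(wrapped), cfg)
  expect_length(res$retained, 0)
  # no keyword: dropped at the keyword stage
  nokw <- ctrl_doc("n", 2500, kw = FALSE, timexes = 6)
  res <- filter_corpus(list(nokw), cfg)
  expect_length(res$retained, 0)
  expect_false(res$docs$pass_keyword)
})

test_that("stage retention is monotone and reports are consistent", {
  corp <- generate_corpus(gen_profile(n_docs = 40, seed = 17,
                                      mean_tokens = 450))$docs
  res <- filter_corpus(corp, filter_config(min_chars = 1500,
                                           min_avg_line_chars = 10,
                                           min_timex_count = 5))
  expect_true(all(res$stages$n_out <= res$stages$n_in))
  expect_identical(res$stages$n_in[-1], res$stages$n_out[-3])
  expect_identical(sum(res$docs$retained), res$stages$n_out[3])
  expect_identical(length(res$retained), res$stages$n_out[3])
})

test_that("the final retained set is invariant under stage order", {
  corp <- generate_corpus(gen_profile(n_docs = 30, seed = 23,
                                      mean_tokens = 500))$docs
  cfgs <- list(c("length", "keyword", "timex"),
               c("timex", "keyword", "length"),
               c("keyword", "timex", "length"))
  sets <- lapply(cfgs, function(ord) {
    res <- filter_corpus(corp, filter_config(min_chars = 1800,
                                             min_avg_line_chars = 10,
                                             min_timex_count = 5,
                                             stage_order = ord))
    sort(vapply(res$retained, `[[`, character(1), "doc_id"))
  })
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
})

test_that("raising any threshold never adds documents", {
  corp <- generate_corpus(gen_profile(n_docs = 25, seed = 31,
                                      mean_tokens = 450))$docs
  base <- filter_corpus(corp, filter_config(min_chars = 1500,
                                            min_avg_line_chars = 5,
                                            min_timex_count = 3))
  ids <- function(res) vapply(res$retained, `[[`, character(1), "doc_id")
  for (cfg in list(filter_config(min_chars = 2500, min_avg_line_chars = 5,
                                 min_timex_count = 3),
                   filter_config(min_chars = 1500, min_avg_line_chars = 40,
                                 min_timex_count = 3),
                   filter_config(min_chars = 1500, min_avg_line_chars = 5,
                                 min_timex_count = 8))) {
    expect_true(all(ids(filter_corpus(corp, cfg)) %in% ids(base)))
  }
})

test_that("percentile mode derives thresholds from the corpus", {
  corp <- c(lapply(c(100, 200, 300, 400), function(n)
    mkdoc(strrep("x", n), paste0("short", n))),
    list(ctrl_doc("big", 800, kw = TRUE, timexes = 8)))
  res <- filter_corpus(corp, filter_config(percentile_mode = TRUE,
                                           min_timex_count = 5))
  # min_chars becomes the 50th percentile (300); only "big" passes all stages
  expect_identical(res$config$min_chars, 300)
  expect_identical(vapply(res$retained, `[[`, character(1), "doc_id"), "big")
})
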