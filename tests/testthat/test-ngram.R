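test_that("tokenization follows the stated rules", {
  expect_equal(
    tokenize("Prazosin and clonidine for moderately severe hypertension")[[1]],
    c("prazosin", "and", "clonidine", "for", "moderately", "severe",
      "hypertension")
  )
  # trailing hyphen stripped, internal hyphen kept
  expect_equal(
    tokenize("Low- and high-dose intravenous insulin therapy")[[1]],
    c("low", "and", "high-dose", "intravenous", "insulin", "therapy")
  )
  expect_equal(tokenize("(?)")[[1]], character(0))
  expect_equal(tokenize("Type 1 diabetes")[[1]], c("type", "1", "diabetes"))
  # en/em dashes separate like hyphens; curly apostrophe retained inside
  expect_equal(tokenize("Crohn’s disease — a review")[[1]],
               c("crohn's", "disease", "a", "review"))
})

test_that("tokenization is idempotent on its own space-joined output", {
  titles <- c(
    "Low- and high-dose intravenous insulin therapy for diabetic ketoacidosis",
    "Effect of beta-blockers (metoprolol) on survival: 10-year follow-up"
  )
  for (t in titles) {
    once <- tokenize(t)[[1]]
    expect_equal(tokenize(paste(once, collapse = " "))[[1]], once)
  }
})

test_that("bigram counts window within titles and denominators pre-date stopword removal", {
  rec <- make_records("Treatment of patients with diabetes", 1980)
  tab2 <- build_frequency_table(rec, 2L)
  expect_equal(sort(rownames(tab2$counts)),
               sort(c("treatment of", "of patients", "patients with",
                      "with diabetes")))
  expect_true(all(tab2$counts == 1L))
  expect_equal(unname(tab2$denominators[["1980"]]), 5)

  tab1 <- build_frequency_table(rec, 1L)  # default stoplist has of, with
  expect_equal(sort(rownames(tab1$counts)),
               c("diabetes", "patients", "treatment"))
  expect_equal(unname(tab1$denominators[["1980"]]), 5)

  # a single-token title contributes no bigrams but one denominator token
  rec2 <- make_records(c("Treatment of patients", "Hypertension"),
                       c(1980, 1980))
  tab <- build_frequency_table(rec2, 2L)
  expect_equal(sum(tab$counts), 2L)      # (3 - 1) + 0
  expect_equal(unname(tab$denominators[["1980"]]), 4)
})

test_that("monogram counts with stopwords retained conserve the denominator", {
  spec <- synthetic_spec(years = 1976:1980, articles_per_year = 60, seed = 5)
  rec <- generate_corpus(spec)$records
  cfg <- tokenizer_config(apply_stopwords_to = "neither")
  tab <- build_frequency_table(rec, 1L, cfg)
  expect_equal(colSums(tab$counts), tab$denominators)
  # denominators shared between orders
  tab2 <- build_frequency_table(rec, 2L, cfg)
  expect_equal(tab$denominators, tab2$denominators)
})

test_that("frequency tables equal a naive per-title recount on random synthetic titles", {
  spec <- synthetic_spec(years = 1990:1994, articles_per_year = 40, seed = 99)
  rec <- generate_corpus(spec)$records[1:200, ]
  cfg <- tokenizer_config()
  for (ord in c(1L, 2L)) {
    tab <- build_frequency_table(rec, ord, cfg)
    oracle <- naive_ngram_count(rec, ord, cfg)
    expect_equal(sum(tab$counts), sum(unlist(oracle)))
    for (key in names(oracle)) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      expect_equal(unname(tab$counts[parts[1], parts[2]]),
                   oracle[[key]])
    }
  }
})

test_that("years without articles carry zero denominators and are reported", {
  rec <- make_records(c("alpha beta", "gamma delta"), c(1976, 1978))
  tab <- build_frequency_table(rec, 1L, years = 1976:1978)
  expect_equal(unname(tab$denominators), c(2, 0, 2))
  s <- get_series(tab, "alpha")
  expect_equal(s$years, c(1976L, 1978L))
  expect_equal(s$dropped_years, 1977L)
})

test_that("per-100k frequencies and absent terms behave as specified", {
  rec <- make_records("alpha beta gamma delta epsilon", 1980)
  tab <- build_frequency_table(rec, 1L)
  expect_equal(get_series(tab, "alpha")$freq, 20000)
  z <- get_series(tab, "missing-term")
  expect_equal(z$freq, 0)
  expect_equal(length(z$freq), length(tab$years))
})

test_that("low-frequency exclusion uses a strict aggregate threshold", {
  tab <- structure(
    list(order = 1L, years = 1976:1977,
         counts = matrix(c(5L, 4L, 6L, 4L), nrow = 2, byrow = TRUE,
                         dimnames = list(c("nine", "ten"),
                                         c("1976", "1977"))),
         denominators = c("1976" = 50000, "1977" = 50000),
         period_total_tokens = 1e5,
         stopwords_version = "x", apply_stopwords_to = "neither"),
    class = "freq_table"
  )
  flt <- low_frequency_filter(tab, 1e-4)
  expect_equal(flt$retained, "ten")        # 10/1e5 = 1e-4 is not < 1e-4
  expect_equal(unname(flt$excluded_counts["nine"]), 9)  # 9e-5 < 1e-4
  expect_error(low_frequency_filter(tab, 0), "threshold")
  expect_error(low_frequency_filter(tab, 1), "threshold")
})

test_that("retention is monotone in the threshold", {
  spec <- synthetic_spec(years = 1976:1980, articles_per_year = 60, seed = 3)
  tab <- build_frequency_table(generate_corpus(spec)$records, 1L)
  th <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.5)
  sets <- lapply(th, function(t) low_frequency_filter(tab, t)$retained)
  for (i in seq_len(length(th) - 1L)) {
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
  expect_lt(length(sets[[5]]), 5)
})

test_that("frequency tables round-trip through TSV + sidecar", {
  spec <- synthetic_spec(years = 1976:1979, articles_per_year = 30, seed = 8)
  tab <- build_frequency_table(generate_corpus(spec)$records, 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(tab, path)
  back <- read_freq_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$denominators, tab$denominators)
  expect_equal(back$order, tab$order)
})
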