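test_that("the same spec and seed reproduce the corpus exactly", {
  spec <- synthetic_spec(years = 1976:1980, articles_per_year = 50, seed = 13)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$true_labels, g2$truth$true_labels)
  # and the generator leaves the session RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_corpus(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("spec validation rejects infeasible frequency targets up front", {
  bad <- tibble::tibble(term = "fading", baseline = 10, slope = -1)
  expect_error(
    synthetic_spec(years = 1976:2015, vocabulary = bad, seed = 1),
    "negative target frequency"
  )
  expect_error(synthetic_spec(years = 1976:1980), "seed")
  mix <- list(list(types = "Journal Article", prob = 0.5))
  expect_error(
    synthetic_spec(years = 1976:1980, pub_type_mix = mix, seed = 1),
    "sum to 1"
  )
})

test_that("generated XML round-trips to field-equal records", {
  spec <- synthetic_spec(years = 1976:1978, articles_per_year = 40, seed = 4)
  rec <- generate_corpus(spec)$records
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(rec, path)
  back <- parse_medline_xml(path)
  expect_equal(back$pmid, rec$pmid)
  expect_equal(back$journal, rec$journal)
  expect_equal(back$year, rec$year)
  expect_equal(back$title, rec$title)
  expect_equal(back$pub_types, rec$pub_types)
})

test_that("special characters survive the XML round-trip", {
  rec <- make_records(
    c("Efficacy of café-au-lait – a trial & more <null>"),
    1980
  )
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(rec, path)
  expect_equal(parse_medline_xml(path)$title, rec$title)
})

test_that("an empty record set writes a valid empty document", {
  rec <- make_records(character(0), integer(0))
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(rec, path)
  back <- parse_medline_xml(path)
  expect_equal(nrow(back), 0L)
})

test_that("per-journal-year splitting partitions the corpus", {
  spec <- synthetic_spec(years = 1976:1977, articles_per_year = 20, seed = 6)
  rec <- generate_corpus(spec)$records
  dir <- withr::local_tempdir()
  files <- write_corpus(rec, dir, split = "journal_year")
  expect_equal(length(files), 2L)
  back <- do.call(rbind, lapply(sort(files), parse_medline_xml))
  expect_equal(sort(as.integer(back$pmid)), sort(as.integer(rec$pmid)))
})

test_that("empirical yearly frequencies track the injected linear targets", {
  # law-of-large-numbers check: b = 50, s = +5, 50k tokens/yr, 40 years
  vocab <- tibble::tibble(term = "grower", baseline = 50, slope = 5)
  spec <- synthetic_spec(years = 1976:2015, vocabulary = vocab,
                         bigrams = trendless(), eras = NULL,
                         patient_centric_fraction_by_era = NULL, seed = 17)
  tab <- simulate_term_counts(spec, tokens_per_year = 50000)
  s <- get_series(tab, "grower")
  target <- 50 + 5 * (s$years - 1976)
  p <- target / 1e5
  sd_freq <- sqrt(p * (1 - p) / 50000) * 1e5
  inside <- abs(s$freq - target) <= 3 * sd_freq
  expect_gte(mean(inside), 0.95)
})

test_that("token-level corpus generation agrees with the frequency-scale path", {
  # the two sampling routes share marginal expectations per term-year
  vocab <- tibble::tibble(term = c("up", "down"), baseline = c(500, 3000),
                          slope = c(50, -50))
  spec <- synthetic_spec(years = 1976:1985, articles_per_year = 600,
                         vocabulary = vocab, bigrams = trendless(),
                         eras = NULL, patient_centric_fraction_by_era = NULL,
                         seed = 23)
  rec <- generate_corpus(spec)$records
  cfg <- tokenizer_config(apply_stopwords_to = "neither")
  tab_tok <- build_frequency_table(rec, 1L, cfg)
  tab_sim <- simulate_term_counts(spec, tokens_per_year =
                                    unname(tab_tok$denominators))
  for (tm in vocab$term) {
    f_tok <- get_series(tab_tok, tm)$freq
    f_sim <- get_series(tab_sim, tm)$freq
    target <- vocab$baseline[vocab$term == tm] +
      vocab$slope[vocab$term == tm] * (1976:1985 - 1976)
    # both routes within 4 binomial SDs of the shared target
    p <- target / 1e5
    sd_freq <- sqrt(p * (1 - p) / tab_tok$denominators) * 1e5
    expect_true(all(abs(f_tok - target) <= 4 * sd_freq))
    expect_true(all(abs(f_sim - target) <= 4 * sd_freq))
  }
})

test_that("injected bigrams appear as adjacent pairs at increasing rates", {
  bg <- tibble::tibble(term = "patients with", baseline = 100, slope = 40)
  spec <- synthetic_spec(years = 1976:1995, articles_per_year = 500,
                         vocabulary = trendless(), bigrams = bg,
                         eras = NULL, patient_centric_fraction_by_era = NULL,
                         seed = 31)
  rec <- generate_corpus(spec)$records
  tab <- build_frequency_table(rec, 2L)
  s <- get_series(tab, "patients with")
  fit <- fit_term_trend(s)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p, 0.01)
})

test_that("ground-truth labels agree with the default classifier on template titles", {
  spec <- synthetic_spec(years = 1976:2015, articles_per_year = 150, seed = 57)
  gen <- generate_corpus(spec)
  ids <- names(gen$truth$true_labels)
  expect_gt(length(ids), 200)
  titles <- gen$records$title[match(ids, gen$records$pmid)]
  cls <- classify_title(titles)
  expect_gte(mean(cls$patient_centric == unname(gen$truth$true_labels)),
             0.99)
})
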