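#' Specification for a synthetic MEDLINE-style corpus
#'
#' Defines a corpus with known ground truth: per-year article counts,
#' titles whose token distribution follows linear-in-year per-term
#' frequencies (baseline + slope, per 100,000 words), injected adjacent
#' word pairs with their own linear rates, a publication-type mix, and
#' template-generated patient-centric vs non-patient-centric clinical
#' trial titles in two era windows. Everything downstream of the seed is
#' deterministic.
#'
#' Frequencies are validated up front: a term whose baseline plus slope
#' times the year offset goes negative anywhere in the range is an error
#' at specification time, not at sampling time. Remaining probability
#' mass in each year falls on a filler vocabulary disjoint from the
#' injected terms, so injected frequencies are exact targets rather than
#' renormalised approximations.
#'
#' @param years inclusive integer year range (default `1976:2015`).
#' @param articles_per_year single integer or per-year vector (default
#'   1257, the scale of one large general-medicine journal).
#' @param title_lengths integer token counts sampled uniformly per title
#'   (default `4:14`).
#' @param vocabulary data frame with columns `term`, `baseline`, `slope`
#'   (per 100,000 words at `min(years)` and per 100,000 words/year);
#'   default [default_trend_vocabulary()].
#' @param bigrams data frame with the same columns, `term` a space-joined
#'   word pair; default [default_trend_bigrams()].
#' @param pub_type_mix list of `list(types = <character>, prob = <num>)`;
#'   probabilities must sum to 1. Default mixes ordinary journal
#'   articles, randomized/controlled trials, comments and reviews.
#' @param journal journal name stamped on every record (default
#'   `"JAMA"`).
#' @param eras named list of inclusive year pairs defining the early and
#'   late classification windows (default 1976-1980 and 2011-2015).
#' @param patient_centric_fraction_by_era named numeric, probability that
#'   a clinical-trial title in each era uses a patient-centric template
#'   (default `c(early = 0.25, late = 0.55)`).
#' @param seed integer random seed (mandatory).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(years = 1976:2015,
                           articles_per_year = 1257L,
                           title_lengths = 4:14,
                           vocabulary = default_trend_vocabulary(),
                           bigrams = default_trend_bigrams(),
                           pub_type_mix = default_pub_type_mix(),
                           journal = "JAMA",
                           eras = list(early = c(1976L, 1980L),
                                       late = c(2011L, 2015L)),
                           patient_centric_fraction_by_era =
                             c(early = 0.25, late = 0.55),
                           seed) {
  if (missing(seed)) stopf("a seed is mandatory for a synthetic_spec")
  seed <- assert_count(seed, "seed", min = 0L)
  years <- sort(unique(as.integer(years)))
  if (length(articles_per_year) == 1L) {
    articles_per_year <- rep(as.integer(articles_per_year), length(years))
  }
  if (length(articles_per_year) != length(years)) {
    stopf("articles_per_year must be length 1 or length(years)")
  }
  if (any(articles_per_year < 0)) stopf("negative articles_per_year")

  vocabulary <- validate_vocab(vocabulary, years, "vocabulary")
  bigrams <- validate_vocab(bigrams, years, "bigrams")
  if (any(vapply(strsplit(bigrams$term, " "), length, integer(1)) != 2L)) {
    stopf("bigram terms must be space-joined word pairs")
  }

  probs <- vapply(pub_type_mix, `[[`, numeric(1), "prob")
  if (any(probs < 0 | probs > 1) || abs(sum(probs) - 1) > 1e-8) {
    stopf("pub_type_mix probabilities must lie in [0,1] and sum to 1")
  }

  pcf <- patient_centric_fraction_by_era
  if (!is.null(eras)) {
    if (is.null(names(eras)) || !setequal(names(eras), names(pcf))) {
      stopf("eras and patient_centric_fraction_by_era must share names")
    }
    if (any(pcf < 0 | pcf > 1)) {
      stopf("patient-centric fractions must lie in [0, 1]")
    }
  }

  structure(
    list(years = years, articles_per_year = articles_per_year,
         title_lengths = as.integer(title_lengths),
         vocabulary = vocabulary, bigrams = bigrams,
         pub_type_mix = pub_type_mix, journal = journal,
         eras = eras, patient_centric_fraction_by_era = pcf,
         seed = seed),
    class = "synthetic_spec"
  )
}

validate_vocab <- function(v, years, what) {
  v <- tibble::as_tibble(v)
  if (!all(c("term", "baseline", "slope") %in% names(v))) {
    stopf("%s must have columns term, baseline, slope", what)
  }
  if (anyDuplicated(v$term)) stopf("%s has duplicated terms", what)
  off <- years - min(years)
  for (i in seq_len(nrow(v))) {
    f <- v$baseline[i] + v$slope[i] * off
    if (any(f < 0)) {
      stopf("%s term '%s' has negative target frequency at year %d",
            what, v$term[i], years[which(f < 0)[1]])
    }
  }
  v
}

#' Default injected monogram trends
#'
#' A small vocabulary of epidemiology-flavoured terms with rising
#' frequencies and case-report-era terms with falling ones; slope
#' magnitudes sit in the range observed for strongly trending title
#' words in large general-medicine journals (units: per 100,000 words
#' per year, baselines at the first study year).
#'
#' @return A tibble with columns `term`, `baseline`, `slope`.
#' @export
default_trend_vocabulary <- function() {
  tibble::tribble(
    ~term,         ~baseline, ~slope,
    "randomized",        30,   20,
    "trial",             80,   15,
    "outcomes",          10,   12,
    "risk",              60,   10.48,
    "association",       40,    8,
    "diabetes",          30,    6.57,
    "care",              50,    5,
    "diabetic",          95,   -2.21,
    "management",       120,   -3,
    "therapy",          200,   -4,
    "report",           250,   -6,
    "cases",            300,   -7
  )
}

#' Default injected bigram trends
#'
#' Word pairs contrasting singular and plural patient reference and
#' causal vs associational phrasing (units as in
#' [default_trend_vocabulary()]).
#'
#' @return A tibble with columns `term`, `baseline`, `slope`.
#' @export
default_trend_bigrams <- function() {
  tibble::tribble(
    ~term,                  ~baseline, ~slope,
    "patients with",              60,  11.37,
    "in patients",                50,   6.92,
    "association between",        10,   4.24,
    "older adults",                5,   2.38,
    "the elderly",                55,  -1.25,
    "a patient",                  70,  -1.66,
    "patient with",               70,  -1.68,
    "caused by",                 100,  -2.42
  )
}

#' Default publication-type mix
#' @return List of `list(types, prob)` entries summing to probability 1.
#' @export
default_pub_type_mix <- function() {
  list(
    list(types = "Journal Article", prob = 0.70),
    list(types = c("Randomized Controlled Trial", "Journal Article"),
         prob = 0.10),
    list(types = c("Clinical Trial", "Journal Article"), prob = 0.05),
    list(types = c("Comment", "Journal Article"), prob = 0.07),
    list(types = c("Review", "Journal Article"), prob = 0.05),
    list(types = c("Letter", "Journal Article"), prob = 0.03)
  )
}

# filler vocabulary: neutral tokens carrying the residual probability
# mass; kept disjoint from injected terms, patient nouns and disease
# adjectives at generation time
filler_vocabulary <- function() {
  sprintf("w%03d", seq_len(150))
}

.template_drugs <- c(
  "prazosin", "clonidine", "beclomethasone", "fluconazole", "aliskiren",
  "erythromycin", "metoprolol", "lisinopril", "warfarin", "aspirin",
  "insulin", "heparin", "prednisone", "amoxicillin", "simvastatin",
  "metformin", "omeprazole", "salbutamol", "digoxin", "furosemide"
)

.template_diseases <- c(
  "hypertension", "diabetes", "asthma", "pneumonia", "candidiasis",
  "migraine", "osteoporosis", "epilepsy", "tuberculosis", "glaucoma",
  "psoriasis", "anemia", "sepsis", "stroke", "lymphoma"
)

# each template is a function(drug, drug2, disease) -> title; the boolean
# marks the ground-truth patient-centric label
.pc_templates <- list(
  function(d, d2, dis) sprintf(
    "Effect of %s on mortality in patients with %s: a randomized clinical trial",
    d, dis),
  function(d, d2, dis) sprintf("%s therapy in adults with %s", d, dis),
  function(d, d2, dis) sprintf(
    "Comparison of %s and %s in children with %s", d, d2, dis),
  function(d, d2, dis) sprintf(
    "%s for women with %s: a randomized clinical trial", d, dis),
  function(d, d2, dis) sprintf(
    "Effect of %s vs %s in men with %s", d, d2, dis)
)

.npc_templates <- list(
  function(d, d2, dis) sprintf("%s for %s", d, dis),
  function(d, d2, dis) sprintf("%s and %s for moderately severe %s",
                               d, d2, dis),
  function(d, d2, dis) sprintf("Effect of %s on %s progression", d, dis),
  function(d, d2, dis) sprintf("%s in the treatment of %s", d, dis),
  function(d, d2, dis) sprintf("Low- and high-dose %s therapy for %s",
                               d, dis)
)

era_of <- function(year, eras) {
  if (is.null(eras)) return(NA_character_)
  for (nm in names(eras)) {
    if (year >= eras[[nm]][1] && year <= eras[[nm]][2]) return(nm)
  }
  NA_character_
}

#' Generate a synthetic corpus with ground truth
#'
#' Builds one record per article. Clinical-trial records falling inside
#' an era window draw a patient-centric or non-patient-centric template
#' title per the era's fraction; all other titles are built by sampling
#' each token slot from the year's term distribution (injected
#' frequencies exact, residual mass on filler words), after which
#' injected word pairs are placed as adjacent pairs at their own
#' year-dependent Poisson rates. The same spec and seed reproduce the
#' record set exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `records` (a record tibble as from
#'   [parse_medline_xml()]) and `truth`: `true_slopes` (named per-term
#'   slopes for injected monograms and bigrams), `true_labels` (named
#'   logical, pmid -> patient-centric, for template titles only),
#'   `record_list` (the records again, per the ground-truth contract).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_rng(spec$seed, {
    years <- spec$years
    y0 <- min(years)

    vocab <- spec$vocabulary
    filler <- setdiff(
      filler_vocabulary(),
      c(vocab$term, unlist(strsplit(spec$bigrams$term, " ")),
        default_patient_nouns(), default_disease_adjectives())
    )

    trial_types <- tolower(pub_type_config()$include)
    mix_probs <- vapply(spec$pub_type_mix, `[[`, numeric(1), "prob")

    pmid <- character(0); yr_out <- integer(0); title <- character(0)
    pub_types <- list()
    labels <- logical(0); label_ids <- character(0)
    next_id <- 1L

    for (iy in seq_along(years)) {
      y <- years[iy]
      n_art <- spec$articles_per_year[iy]
      if (n_art == 0L) next

      mix_idx <- sample.int(length(spec$pub_type_mix), n_art,
                            replace = TRUE, prob = mix_probs)
      types <- lapply(spec$pub_type_mix[mix_idx], `[[`, "types")
      is_trial <- vapply(types, function(tt) {
        any(tolower(tt) %in% trial_types)
      }, logical(1))

      era <- era_of(y, spec$eras)
      templated <- if (!is.na(era)) is_trial else rep(FALSE, n_art)

      # term probabilities for this year
      p_term <- (vocab$baseline + vocab$slope * (y - y0)) / 1e5
      p_fill <- (1 - sum(p_term)) / length(filler)
      if (p_fill < 0) stopf("injected vocabulary mass exceeds 1 in %d", y)
      pool <- c(vocab$term, filler)
      pool_p <- c(p_term, rep(p_fill, length(filler)))

      lens <- sample(spec$title_lengths, n_art, replace = TRUE)
      titles_y <- character(n_art)

      n_tok_sampled <- sum(lens[!templated])
      if (n_tok_sampled > 0) {
        draws <- sample(pool, n_tok_sampled, replace = TRUE, prob = pool_p)
        tok_titles <- split(draws, rep(which(!templated), lens[!templated]))
      } else {
        tok_titles <- list()
      }

      # adjacent-pair injection at per-year Poisson rates
      if (nrow(spec$bigrams) > 0 && length(tok_titles) > 0) {
        long_idx <- which(lengths(tok_titles) >= 2L)
        n_tok_y <- sum(lengths(tok_titles))
        for (ib in seq_len(nrow(spec$bigrams))) {
          rate <- (spec$bigrams$baseline[ib] +
                     spec$bigrams$slope[ib] * (y - y0)) / 1e5
          m <- stats::rpois(1, rate * n_tok_y)
          if (m == 0L || length(long_idx) == 0L) next
          pair <- strsplit(spec$bigrams$term[ib], " ")[[1]]
          at <- sample(long_idx, m, replace = TRUE)
          for (ti in at) {
            tt <- tok_titles[[ti]]
            pos <- sample.int(length(tt) - 1L, 1L)
            tt[pos] <- pair[1]; tt[pos + 1L] <- pair[2]
            tok_titles[[ti]] <- tt
          }
        }
      }

      for (ti in names(tok_titles)) {
        i <- as.integer(ti)
        titles_y[i] <- paste(tok_titles[[ti]], collapse = " ")
      }

      # template titles for trial records inside an era window
      if (any(templated)) {
        frac <- spec$patient_centric_fraction_by_era[[era]]
        for (i in which(templated)) {
          pc <- stats::runif(1) < frac
          tpl_set <- if (pc) .pc_templates else .npc_templates
          tpl <- tpl_set[[sample.int(length(tpl_set), 1L)]]
          dd <- sample(.template_drugs, 2L)
          dis <- sample(.template_diseases, 1L)
          titles_y[i] <- tpl(dd[1], dd[2], dis)
          labels <- c(labels, pc)
          label_ids <- c(label_ids, as.character(next_id + i - 1L))
        }
      }

      pmid <- c(pmid, as.character(seq(next_id, next_id + n_art - 1L)))
      next_id <- next_id + n_art
      yr_out <- c(yr_out, rep(y, n_art))
      title <- c(title, titles_y)
      pub_types <- c(pub_types, types)
    }

    records <- tibble::tibble(
      pmid = pmid, journal = spec$journal, year = yr_out,
      title = title, pub_types = pub_types
    )
    slopes <- c(
      setNames(vocab$slope, vocab$term),
      setNames(spec$bigrams$slope, spec$bigrams$term)
    )
    list(
      records = records,
      truth = list(
        true_slopes = slopes,
        true_labels = setNames(labels, label_ids),
        record_list = records
      )
    )
  })
}

#' Simulate per-year term counts directly on the frequency scale
#'
#' Draws each year's term counts from one multinomial over the spec's
#' injected monogram probabilities plus a filler remainder, skipping
#' title assembly. The marginal count distribution per term-year is the
#' same as generating titles token-by-token and counting, which makes
#' this the workhorse for calibration studies (slope recovery, FDR
#' control, type-I error) at realistic token volumes.
#'
#' @param spec a [synthetic_spec()] (only `years`, `vocabulary` and
#'   `seed` are used).
#' @param tokens_per_year total tokens per year (single value or
#'   per-year vector); default `articles_per_year * mean(title_lengths)`
#'   rounded.
#' @param seed overrides `spec$seed` when given (useful for replicates).
#' @return A `freq_table` of order 1 whose rows are the injected terms
#'   plus a `".filler"` remainder row, so column sums equal the
#'   denominators.
#' @export
simulate_term_counts <- function(spec, tokens_per_year = NULL, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  years <- spec$years
  if (is.null(tokens_per_year)) {
    tokens_per_year <- round(spec$articles_per_year *
                               mean(spec$title_lengths))
  }
  if (length(tokens_per_year) == 1L) {
    tokens_per_year <- rep(tokens_per_year, length(years))
  }
  with_preserved_rng(seed %||% spec$seed, {
    vocab <- spec$vocabulary
    y0 <- min(years)
    counts <- matrix(0L, nrow = nrow(vocab) + 1L, ncol = length(years),
                     dimnames = list(c(vocab$term, ".filler"),
                                     as.character(years)))
    for (iy in seq_along(years)) {
      p <- (vocab$baseline + vocab$slope * (years[iy] - y0)) / 1e5
      if (sum(p) > 1) stopf("injected mass exceeds 1 in %d", years[iy])
      counts[, iy] <- stats::rmultinom(1, tokens_per_year[iy],
                                       c(p, 1 - sum(p)))[, 1]
    }
    denom <- setNames(as.numeric(tokens_per_year), years)
    structure(
      list(order = 1L, years = years, counts = counts,
           denominators = denom, period_total_tokens = sum(denom),
           stopwords_version = "none", apply_stopwords_to = "neither"),
      class = "freq_table"
    )
  })
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write records as MEDLINE-dialect XML
#'
#' Emits a `PubmedArticleSet` document that parses back through
#' [parse_medline_xml()] to field-equal records (the round-trip
#' contract). Titles are UTF-8 with XML special characters escaped. An
#' empty record set yields a valid empty document.
#'
#' @param records a record tibble.
#' @param path output file, or output directory when
#'   `split = "journal_year"`.
#' @param split `"none"` (one file, default) or `"journal_year"` (one
#'   file per journal-year under `path`).
#' @return The path(s) written, invisibly.
#' @export
write_corpus <- function(records, path, split = c("none", "journal_year")) {
  split <- match.arg(split)
  if (split == "journal_year") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    key <- paste(gsub("[^A-Za-z0-9]+", "_", records$journal),
                 records$year, sep = "_")
    files <- character(0)
    for (k in unique(key)) {
      f <- file.path(path, paste0(k, ".xml"))
      write_corpus(records[key == k, , drop = FALSE], f, split = "none")
      files <- c(files, f)
    }
    return(invisible(files))
  }

  rec_xml <- if (nrow(records) == 0L) character(0) else vapply(
    seq_len(nrow(records)),
    function(i) {
      pts <- paste0(
        "<PublicationType>", xml_escape(records$pub_types[[i]]),
        "</PublicationType>",
        collapse = ""
      )
      paste0(
        "<PubmedArticle><MedlineCitation><PMID>",
        xml_escape(records$pmid[i]), "</PMID><Article>",
        "<Journal><Title>", xml_escape(records$journal[i]),
        "</Title><JournalIssue><PubDate><Year>", records$year[i],
        "</Year></PubDate></JournalIssue></Journal>",
        "<ArticleTitle>", xml_escape(records$title[i]), "</ArticleTitle>",
        "<PublicationTypeList>", pts, "</PublicationTypeList>",
        "</Article></MedlineCitation></PubmedArticle>"
      )
    },
    character(1)
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(
    c('<?xml version="1.0" encoding="UTF-8"?>',
      "<PubmedArticleSet>", rec_xml, "</PubmedArticleSet>"),
    con, useBytes = FALSE
  )
  invisible(path)
}
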