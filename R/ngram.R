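#' Stopword list shipped with the package
#'
#' The fixed, versioned list of 174 common English function words removed
#' before monogram counting (bigrams keep them for their contextual
#' relevance). The list file is part of the reproducibility surface; its
#' version tag travels with every frequency table built from it.
#'
#' @return Character vector of lowercase stopwords with attribute
#'   `"version"`.
#' @export
default_stopwords <- function() {
  if (is.null(.tt_cache$stopwords)) {
    sw <- readLines(pkg_file("extdata", "stopwords_english_v1.txt"),
                    encoding = "UTF-8")
    sw <- sw[nzchar(sw)]
    attr(sw, "version") <- "english_v1"
    .tt_cache$stopwords <- sw
  }
  .tt_cache$stopwords
}

#' Tokenizer configuration
#'
#' Tokens are maximal runs of letters/digits with internal hyphens and
#' apostrophes retained; all other punctuation separates. En/em dashes are
#' normalised to plain hyphens and curly apostrophes to straight ones
#' before matching, so "low- and high-dose" tokenizes to
#' `low, and, high-dose`. Digits and single-letter tokens are retained
#' (so "type 1" survives).
#'
#' @param lowercase lowercase all tokens (default `TRUE`).
#' @param stopwords lowercase stopword vector; defaults to the shipped
#'   174-word English list ([default_stopwords()]).
#' @param apply_stopwords_to one of `"monograms_only"` (default: stopwords
#'   removed before monogram counting but kept in bigrams), `"both"`, or
#'   `"neither"`.
#' @return An object of class `tokenizer_config`.
#' @export
tokenizer_config <- function(lowercase = TRUE,
                             stopwords = default_stopwords(),
                             apply_stopwords_to = c("monograms_only",
                                                    "both", "neither")) {
  assert_flag(lowercase, "lowercase")
  apply_stopwords_to <- match.arg(apply_stopwords_to)
  stopwords_version <- attr(stopwords, "version") %||% "custom"
  stopwords <- as.character(stopwords)
  if (any(stopwords != tolower(stopwords))) {
    stopf("stopword list must be lowercase")
  }
  structure(
    list(lowercase = lowercase, stopwords = stopwords,
         stopwords_version = stopwords_version,
         apply_stopwords_to = apply_stopwords_to),
    class = "tokenizer_config"
  )
}

.token_regex <- "[\\p{L}\\p{N}]+(?:['-][\\p{L}\\p{N}]+)*"

#' Tokenize titles
#'
#' Deterministic tokenization: dash variants are normalised to `-`, curly
#' apostrophes to `'`, text is lowercased if configured, and tokens are
#' maximal runs of letters/digits with internal hyphens/apostrophes
#' retained (leading/trailing ones are stripped because the pattern
#' requires an alphanumeric on both sides). A title with no admissible
#' tokens yields an empty token vector.
#'
#' @param x character vector of titles.
#' @param cfg a [tokenizer_config()].
#' @return A list of character vectors, one per element of `x`.
#' @examples
#' tokenize("Prazosin and clonidine for moderately severe hypertension")
#' @export
tokenize <- function(x, cfg = tokenizer_config()) {
  stopifnot(inherits(cfg, "tokenizer_config"))
  x <- as.character(x)
  # dash variants (hyphen/figure/en/em/horizontal bar, minus) -> hyphen;
  # right single quotation mark -> apostrophe
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014\u2015\u2212]", "-", x)
  x <- gsub("\u2019", "'", x)
  if (cfg$lowercase) x <- tolower(x)
  m <- gregexpr(.token_regex, x, perl = TRUE)
  toks <- regmatches(x, m)
  lapply(toks, function(t) if (length(t) == 1L && t[1] == "") character(0) else t)
}

#' Build a per-year monogram or bigram frequency table
#'
#' Counts terms over all titles grouped by publication year. Bigrams are
#' adjacent token pairs within a single title, never across titles.
#' Stop-word removal is applied per `cfg$apply_stopwords_to` before
#' counting, but the per-year denominators `N_y` always count tokens
#' before any removal and are therefore identical between the monogram and
#' bigram tables built from the same records. Years inside `years` with
#' no articles appear with `N_y = 0`.
#'
#' @param records a record tibble with columns `year` and `title`.
#' @param order n-gram order, 1 (monograms) or 2 (bigrams).
#' @param cfg a [tokenizer_config()].
#' @param years integer vector of years the table must span; defaults to
#'   the full range of `records$year`.
#' @return An object of class `freq_table`: a list with `order`, `years`,
#'   `counts` (integer matrix, terms x years), `denominators` (named
#'   per-year token totals), `period_total_tokens`, and the tokenizer
#'   provenance (`stopwords_version`, `apply_stopwords_to`).
#' @export
build_frequency_table <- function(records, order, cfg = tokenizer_config(),
                                  years = NULL) {
  if (!order %in% c(1L, 2L)) stopf("order must be 1 or 2")
  if (nrow(records) == 0L) stopf("no records to count")
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  years <- sort(unique(as.integer(years)))
  if (!all(records$year %in% years)) {
    stopf("records contain years outside the declared range")
  }

  toks <- tokenize(records$title, cfg)
  n_tok <- lengths(toks)

  # denominators: all tokens, pre stop-word removal
  denom <- setNames(numeric(length(years)), years)
  agg <- tapply(n_tok, records$year, sum)
  denom[names(agg)] <- agg

  remove_sw <- switch(cfg$apply_stopwords_to,
    monograms_only = order == 1L, both = TRUE, neither = FALSE
  )
  if (remove_sw) {
    toks <- lapply(toks, function(t) t[!(t %in% cfg$stopwords)])
  }

  if (order == 2L) {
    toks <- lapply(toks, function(t) {
      n <- length(t)
      if (n < 2L) character(0) else paste(t[-n], t[-1L])
    })
  }

  len <- lengths(toks)
  term <- unlist(toks, use.names = FALSE)
  yr <- rep(records$year, len)

  if (length(term) == 0L) {
    counts <- matrix(0L, nrow = 0L, ncol = length(years),
                     dimnames = list(character(0), as.character(years)))
  } else {
    dt <- data.table::data.table(term = term, year = yr)
    tab <- dt[, .N, by = c("term", "year")]
    terms <- sort(unique(tab$term))
    counts <- matrix(0L, nrow = length(terms), ncol = length(years),
                     dimnames = list(terms, as.character(years)))
    counts[cbind(match(tab$term, terms),
                 match(tab$year, years))] <- tab$N
  }

  structure(
    list(order = as.integer(order), years = years, counts = counts,
         denominators = denom, period_total_tokens = sum(denom),
         stopwords_version = cfg$stopwords_version,
         apply_stopwords_to = cfg$apply_stopwords_to),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf(
    "<freq_table> order %d: %d terms x %d years (%d-%d), %s tokens total\n",
    x$order, nrow(x$counts), length(x$years), min(x$years), max(x$years),
    format(x$period_total_tokens, big.mark = ",")
  ))
  invisible(x)
}

#' Drop terms of very low aggregate frequency
#'
#' A term is retained iff its pooled count over the whole period, divided
#' by the pooled token total, is at least `threshold`; strictly smaller
#' aggregate frequencies are excluded. The default 1e-4 is the "<0.01%
#' within the study period" rule. Retention is monotone in the threshold.
#'
#' @param table a `freq_table`.
#' @param threshold aggregate-frequency cutoff in (0, 1); default `1e-4`.
#' @return A list with `retained` (character vector of terms),
#'   `excluded_counts` (named aggregate counts of excluded terms) and
#'   `n_excluded`.
#' @export
low_frequency_filter <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "freq_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stopf("threshold must lie in (0, 1)")
  }
  if (table$period_total_tokens <= 0) {
    stopf("period_total_tokens must be positive")
  }
  agg <- rowSums(table$counts)
  keep <- (agg / table$period_total_tokens) >= threshold
  list(
    retained = rownames(table$counts)[keep],
    excluded_counts = agg[!keep],
    n_excluded = sum(!keep)
  )
}

#' Extract a per-year frequency series for one term
#'
#' Frequencies are `100000 * c_ty / N_y` (occurrences per 100,000 title
#' words). Years with a zero denominator are dropped from the series and
#' listed in the `dropped_years` attribute. A term absent from the table
#' yields an all-zero series over the table's non-empty years.
#'
#' @param table a `freq_table`.
#' @param term term string (for bigrams, the space-joined pair).
#' @return An object of class `term_series`: list with `term`, `years`,
#'   `freq`, and attribute-like field `dropped_years`.
#' @export
get_series <- function(table, term) {
  stopifnot(inherits(table, "freq_table"))
  denom <- table$denominators
  nonzero <- denom > 0
  cnt <- if (term %in% rownames(table$counts)) {
    table$counts[term, ]
  } else {
    setNames(numeric(length(table$years)), as.character(table$years))
  }
  structure(
    list(
      term = term,
      years = table$years[nonzero],
      freq = 1e5 * as.numeric(cnt[nonzero]) / as.numeric(denom[nonzero]),
      dropped_years = table$years[!nonzero]
    ),
    class = "term_series"
  )
}

#' Write a frequency table as long-format TSV with a JSON sidecar
#'
#' The TSV has columns `order, term, year, count, denominator`; the
#' sidecar records the n-gram order, stopword-list version, stopword
#' policy and period token total so a table can be reproduced and
#' reloaded exactly.
#'
#' @param table a `freq_table`.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  idx <- which(table$counts > 0, arr.ind = TRUE)
  df <- data.frame(
    order = table$order,
    term = rownames(table$counts)[idx[, 1]],
    year = table$years[idx[, 2]],
    count = table$counts[idx],
    denominator = as.numeric(table$denominators[idx[, 2]])
  )
  df <- df[order(df$term, df$year), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    order = table$order,
    years = table$years,
    denominators = as.list(table$denominators),
    period_total_tokens = table$period_total_tokens,
    stopwords_version = table$stopwords_version,
    apply_stopwords_to = table$apply_stopwords_to
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a frequency table written by [write_freq_table()]
#'
#' @param path TSV path (the `<path>.json` sidecar must sit beside it).
#' @return A `freq_table`.
#' @export
read_freq_table <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          colClasses = c("integer", "character", "integer",
                                         "integer", "numeric"))
  years <- as.integer(side$years)
  denom <- setNames(numeric(length(years)), years)
  denom[names(side$denominators)] <- unlist(side$denominators)
  terms <- sort(unique(df$term))
  counts <- matrix(0L, nrow = length(terms), ncol = length(years),
                   dimnames = list(terms, as.character(years)))
  if (nrow(df)) {
    counts[cbind(match(df$term, terms), match(df$year, years))] <- df$count
  }
  structure(
    list(order = as.integer(side$order), years = years, counts = counts,
         denominators = denom,
         period_total_tokens = side$period_total_tokens,
         stopwords_version = side$stopwords_version,
         apply_stopwords_to = side$apply_stopwords_to),
    class = "freq_table"
  )
}
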