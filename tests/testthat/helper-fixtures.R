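# Shared fixtures and independent oracles, built in code at test time.

# one PubmedArticle element; pass year = NULL to omit PubDate/Year,
# medline_date to use a MedlineDate instead, title = NULL to omit it
medline_article <- function(pmid = "1", title = "A study", year = 1980,
                            medline_date = NULL, journal = "JAMA",
                            pub_types = "Journal Article") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  date <- if (!is.null(medline_date)) {
    sprintf("<MedlineDate>%s</MedlineDate>", medline_date)
  } else if (!is.null(year)) {
    sprintf("<Year>%d</Year>", year)
  } else ""
  ttl <- if (is.null(title)) "" else {
    sprintf("<ArticleTitle>%s</ArticleTitle>", esc(title))
  }
  pts <- paste0("<PublicationType>", esc(pub_types), "</PublicationType>",
                collapse = "")
  paste0(
    "<PubmedArticle><MedlineCitation><PMID>", pmid, "</PMID><Article>",
    "<Journal><Title>", esc(journal), "</Title><JournalIssue><PubDate>",
    date, "</PubDate></JournalIssue></Journal>", ttl,
    "<PublicationTypeList>", pts, "</PublicationTypeList>",
    "</Article></MedlineCitation></PubmedArticle>"
  )
}

medline_set <- function(...) {
  paste0("<PubmedArticleSet>", paste0(..., collapse = ""),
         "</PubmedArticleSet>")
}

make_records <- function(titles, years, journal = "JAMA",
                         pub_types = "Journal Article") {
  tibble::tibble(
    pmid = as.character(seq_along(titles)),
    journal = journal,
    year = as.integer(years),
    title = titles,
    pub_types = replicate(length(titles), pub_types, simplify = FALSE)
  )
}

# naive per-title sliding-window n-gram recount, independent of the
# data.table counting path
naive_ngram_count <- function(records, order, cfg = tokenizer_config()) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    t <- tokenize(records$title[i], cfg)[[1]]
    if (order == 1L && cfg$apply_stopwords_to %in% c("monograms_only", "both")) {
      t <- t[!(t %in% cfg$stopwords)]
    }
    if (order == 2L && cfg$apply_stopwords_to == "both") {
      t <- t[!(t %in% cfg$stopwords)]
    }
    grams <- if (order == 1L) t else {
      if (length(t) < 2L) character(0) else {
        vapply(seq_len(length(t) - 1L),
               function(j) paste(t[j], t[j + 1L]), character(1))
      }
    }
    for (g in grams) {
      key <- paste(g, records$year[i], sep = "\r")
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook step-up BH adjustment, written directly from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  cummin_rev <- Inf
  for (i in rev(seq_len(m))) {
    cummin_rev <- min(cummin_rev, min(1, p[ord[i]] * m / i))
    q[ord[i]] <- cummin_rev
  }
  q
}

# brute-force least squares, independent of the closed-form path: for any
# fixed slope b the SSE-optimal intercept is mean(y - b*xc), so minimise
# the profiled SSE by root-finding its derivative numerically
brute_force_ols <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  dsse <- function(b) -2 * sum((yc - b * xc) * xc)
  bound <- sum(abs(yc) * abs(xc)) / sum(xc^2) + 1
  b <- uniroot(dsse, c(-bound, bound), tol = 1e-14)$root
  c(intercept0 = mean(y) - b * mean(x), slope = b)
}

trendless <- function() {
  tibble::tibble(term = character(0), baseline = numeric(0),
                 slope = numeric(0))
}
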