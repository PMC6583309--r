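#' Fit the continuous linear trend model for one term
#'
#' Ordinary least squares of yearly frequency (per 100,000 words) on
#' calendar year with an intercept. The slope is the mean annual change
#' in frequency; `total_change` is the slope times the year span. The
#' two-tailed p-value uses the t distribution with `n_years - 2` degrees
#' of freedom and the 95% CI is `slope +/- t_{0.975, n-2} * se`.
#'
#' A perfect fit (residual sum of squares numerically zero) is degenerate:
#' the p-value is 0 when the slope is nonzero and 1 when it is zero, with
#' `se = 0` and a point CI.
#'
#' @param series a `term_series` from [get_series()], or any list with
#'   numeric `years` and `freq` of equal length (and optionally `term`).
#' @return A one-row [tibble::tibble] with columns `term`, `slope`,
#'   `intercept` (fitted frequency at the first year), `se`, `ci_low`,
#'   `ci_high`, `t`, `p`, `q` (`NA` until a family-wise [bh_adjust()]),
#'   `total_change`, `n_years`.
#' @examples
#' fit_term_trend(list(term = "x", years = 2000:2003, freq = c(1, 2, 2, 3)))
#' @export
fit_term_trend <- function(series) {
  x <- as.numeric(series$years)
  y <- as.numeric(series$freq)
  n <- length(x)
  if (n != length(y)) stopf("years and freq lengths differ")
  if (n < 3L) stopf("need at least 3 years to fit a trend (got %d)", n)
  if (length(unique(x)) == 1L) stopf("constant year vector")

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- sum(xc * y) / sxx
  alpha0 <- mean(y) - beta * mean(x)            # intercept at year 0
  sse <- sum((y - alpha0 - beta * x)^2)
  df <- n - 2L

  eps <- 1e-12 * max(1, sum(y^2))
  if (sse <= eps) {
    se <- 0; tval <- if (beta == 0) 0 else sign(beta) * Inf
    p <- if (beta == 0) 1 else 0
    ci <- c(beta, beta)
  } else {
    se <- sqrt(sse / df / sxx)
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
    ci <- beta + c(-1, 1) * qt(0.975, df) * se
  }

  tibble::tibble(
    term = series$term %||% NA_character_,
    slope = beta,
    intercept = alpha0 + beta * min(x),
    se = se, ci_low = ci[1], ci_high = ci[2],
    t = tval, p = p, q = NA_real_,
    total_change = beta * (max(x) - min(x)),
    n_years = n
  )
}

#' Benjamini-Hochberg adjusted values
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} min(1, p_j * m / j)`, returned in the original
#' order. Values at or below the FDR threshold (0.01 throughout this
#' pipeline) mark significant trends.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(pvalues, method = "BH")
}

#' Mass-univariate trend screen over a frequency table
#'
#' Applies the low-frequency exclusion, fits the linear trend model to
#' every retained term (vectorised closed-form OLS identical to
#' [fit_term_trend()]), adjusts the p-values by Benjamini-Hochberg within
#' this table's family (monograms and bigrams are corrected separately
#' when screened as separate tables; pool them yourself before calling
#' [bh_adjust()] if a joint correction is wanted), and ranks the top-k
#' increased and decreased terms among those with `q < fdr_threshold`.
#' Slope ties are broken lexicographically by term. Years with a zero
#' token denominator are dropped from every series.
#'
#' @param table a `freq_table`.
#' @param fdr_threshold FDR significance threshold (default 0.01).
#' @param k length of the top-increased/decreased rankings (default 20).
#' @param low_freq_threshold aggregate-frequency exclusion threshold
#'   passed to [low_frequency_filter()] (default 1e-4); `NULL` skips the
#'   filter (use when the table is already filtered).
#' @return An object of class `screen_report`: list with `results` (one
#'   row per retained term, columns as in [fit_term_trend()] plus `q`),
#'   `fdr_threshold`, `k`, `top_increased`, `top_decreased` (tibbles of
#'   significant terms sorted by slope), `n_excluded_low_freq`,
#'   `dropped_years`.
#' @export
screen <- function(table, fdr_threshold = 0.01, k = 20L,
                   low_freq_threshold = 1e-4) {
  stopifnot(inherits(table, "freq_table"))
  k <- assert_count(k, "k")
  if (fdr_threshold < 0 || fdr_threshold > 1) {
    stopf("fdr_threshold must lie in [0, 1]")
  }

  if (is.null(low_freq_threshold)) {
    retained <- rownames(table$counts)
    n_excl <- 0L
  } else {
    flt <- low_frequency_filter(table, low_freq_threshold)
    retained <- flt$retained
    n_excl <- flt$n_excluded
  }
  if (length(retained) == 0L) stopf("no terms retained for screening")

  nonzero <- table$denominators > 0
  x <- as.numeric(table$years[nonzero])
  n <- length(x)
  if (n < 3L) stopf("need at least 3 years with articles (got %d)", n)

  cnt <- table$counts[retained, nonzero, drop = FALSE]
  fmat <- sweep(cnt, 2L, as.numeric(table$denominators[nonzero]), "/") * 1e5

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- as.numeric(fmat %*% xc) / sxx
  ybar <- rowMeans(fmat)
  alpha0 <- ybar - beta * mean(x)
  fitted <- outer(beta, x) + alpha0
  sse <- rowSums((fmat - fitted)^2)
  df <- n - 2L

  se <- sqrt(sse / df / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  tq <- qt(0.975, df)
  ci_low <- beta - tq * se
  ci_high <- beta + tq * se

  # degenerate perfect fits
  eps <- 1e-12 * pmax(1, rowSums(fmat^2))
  dg <- sse <= eps
  if (any(dg)) {
    se[dg] <- 0
    tval[dg] <- ifelse(beta[dg] == 0, 0, sign(beta[dg]) * Inf)
    p[dg] <- ifelse(beta[dg] == 0, 1, 0)
    ci_low[dg] <- beta[dg]; ci_high[dg] <- beta[dg]
  }

  res <- tibble::tibble(
    term = retained, slope = beta,
    intercept = alpha0 + beta * min(x),
    se = se, ci_low = ci_low, ci_high = ci_high,
    t = tval, p = p, q = bh_adjust(p),
    total_change = beta * (max(x) - min(x)),
    n_years = n
  )

  sig <- res[res$q < fdr_threshold, , drop = FALSE]
  up <- sig[sig$slope > 0, , drop = FALSE]
  up <- up[order(-up$slope, up$term), , drop = FALSE]
  down <- sig[sig$slope < 0, , drop = FALSE]
  down <- down[order(down$slope, down$term), , drop = FALSE]

  structure(
    list(
      results = res, fdr_threshold = fdr_threshold, k = k,
      top_increased = head(up, k), top_decreased = head(down, k),
      n_excluded_low_freq = n_excl,
      dropped_years = table$years[!nonzero]
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  n_sig <- sum(x$results$q < x$fdr_threshold)
  cat(sprintf(
    "<screen_report> %d terms screened, %d significant at FDR < %g\n",
    nrow(x$results), n_sig, x$fdr_threshold
  ))
  if (nrow(x$top_increased)) {
    cat("top increased:",
        paste(head(x$top_increased$term, 5), collapse = ", "), "\n")
  }
  if (nrow(x$top_decreased)) {
    cat("top decreased:",
        paste(head(x$top_decreased$term, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Word-cloud weights for significant terms
#'
#' Weight = |slope| * year span, the magnitude of the absolute change in
#' frequency over the study period; terms not significant at the report's
#' FDR threshold are absent. The weights feed any word-cloud renderer;
#' layout is out of scope.
#'
#' @param report a `screen_report`.
#' @param year_span span in years (e.g. 39 for a 1976-2015 study period).
#' @return Named numeric vector of weights.
#' @export
cloud_weights <- function(report, year_span) {
  stopifnot(inherits(report, "screen_report"))
  year_span <- assert_count(year_span, "year_span")
  sig <- report$results[report$results$q < report$fdr_threshold, ,
                        drop = FALSE]
  setNames(abs(sig$slope) * year_span, sig$term)
}

#' Write a screen report to disk
#'
#' Emits the full results as TSV (term, slope, se, ci_low, ci_high, t, p,
#' q, total_change), the top-k lists as JSON, and (optionally) cloud
#' weights as a two-column TSV.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix, e.g. `"monograms"`.
#' @param year_span if non-`NULL`, also write `<prefix>_cloud_weights.tsv`
#'   computed with [cloud_weights()].
#' @return The directory, invisibly.
#' @export
write_screen_report <- function(report, dir, prefix = "terms",
                                year_span = NULL) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$results[order(report$results$q, report$results$p,
                              report$results$term), ]
  utils::write.table(
    res[, c("term", "slope", "se", "ci_low", "ci_high", "t", "p", "q",
            "total_change")],
    file.path(dir, paste0(prefix, "_screen.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      fdr_threshold = report$fdr_threshold, k = report$k,
      top_increased = report$top_increased,
      top_decreased = report$top_decreased
    ),
    file.path(dir, paste0(prefix, "_top.json")),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(year_span)) {
    w <- cloud_weights(report, year_span)
    utils::write.table(
      data.frame(term = names(w), weight = as.numeric(w)),
      file.path(dir, paste0(prefix, "_cloud_weights.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(dir)
}
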