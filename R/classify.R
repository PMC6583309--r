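#' Patient-centric classification rule set
#'
#' A title is patient-centric when it contains a noun referring to the
#' patient or study population that is independent of a disease label:
#' "patients with diabetes" qualifies, "diabetic ketoacidosis" does not.
#' The independence rule disqualifies a patient noun immediately
#' premodified by a disease adjective ("diabetic patients"), mirroring
#' the separation of patient and disease the classification probes.
#' Every classification output carries `version` so alternative rule sets
#' remain comparable.
#'
#' @param patient_nouns lowercase nouns denoting patients or study
#'   populations.
#' @param disease_adjectives lowercase adjectives that characterise a
#'   person by a disease.
#' @param independence_rule apply the premodifier disqualification
#'   (default `TRUE`).
#' @param version rule-set version string (non-empty).
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(patient_nouns = default_patient_nouns(),
                     disease_adjectives = default_disease_adjectives(),
                     independence_rule = TRUE,
                     version = "pc-rules-v1") {
  assert_flag(independence_rule, "independence_rule")
  if (!nzchar(version)) stopf("rule-set version must be non-empty")
  patient_nouns <- as.character(patient_nouns)
  disease_adjectives <- as.character(disease_adjectives)
  if (length(patient_nouns) == 0L) stopf("empty patient-noun lexicon")
  if (any(patient_nouns != tolower(patient_nouns)) ||
      any(disease_adjectives != tolower(disease_adjectives))) {
    stopf("rule-set lexicons must be lowercase")
  }
  structure(
    list(patient_nouns = patient_nouns,
         disease_adjectives = disease_adjectives,
         independence_rule = independence_rule, version = version),
    class = "rule_set"
  )
}

#' Default patient-noun lexicon
#' @return Lowercase character vector.
#' @export
default_patient_nouns <- function() {
  c("patient", "patients", "adult", "adults", "child", "children",
    "woman", "women", "man", "men", "infant", "infants", "neonates",
    "newborns", "adolescents", "participants", "survivors", "volunteers")
}

#' Default disease-adjective lexicon
#' @return Lowercase character vector.
#' @export
default_disease_adjectives <- function() {
  c("diabetic", "asthmatic", "hypertensive", "epileptic", "schizophrenic",
    "anemic", "anaemic", "arthritic", "cirrhotic", "uremic", "uraemic",
    "septic", "obese", "depressed", "demented")
}

#' Classify titles as patient-centric or not
#'
#' A title is labelled patient-centric iff at least one patient-noun
#' token survives the independence rule. Matching is on lowercased
#' tokens, so it is invariant to case and to punctuation surrounding the
#' matched words. Evidence lists every matched noun and any disqualifying
#' premodifier.
#'
#' @param titles character vector of titles.
#' @param rules a [rule_set()].
#' @return A [tibble::tibble] with columns `title`, `patient_centric`
#'   (logical), `evidence` (list: qualifying nouns), `disqualified`
#'   (list: "adjective noun" pairs suppressed by the independence rule),
#'   `rules_version`.
#' @examples
#' classify_title("Prazosin and clonidine for moderately severe hypertension")
#' @export
classify_title <- function(titles, rules = rule_set()) {
  stopifnot(inherits(rules, "rule_set"))
  cfg <- tokenizer_config(stopwords = character(0))
  toks <- tokenize(titles, cfg)
  out <- lapply(toks, function(t) {
    hit <- which(t %in% rules$patient_nouns)
    if (rules$independence_rule && length(hit)) {
      premod <- hit > 1L & t[pmax(hit - 1L, 1L)] %in% rules$disease_adjectives
    } else {
      premod <- rep(FALSE, length(hit))
    }
    list(
      evidence = t[hit[!premod]],
      disqualified = if (any(premod)) {
        paste(t[hit[premod] - 1L], t[hit[premod]])
      } else character(0)
    )
  })
  tibble::tibble(
    title = titles,
    patient_centric = vapply(out, function(o) length(o$evidence) > 0L,
                             logical(1)),
    evidence = lapply(out, `[[`, "evidence"),
    disqualified = lapply(out, `[[`, "disqualified"),
    rules_version = rules$version
  )
}

#' Construct a rater annotation set
#'
#' @param rater_id rater identifier.
#' @param labels logical vector of patient-centric labels, named by
#'   title id; no missing values.
#' @param blinded whether the rater saw titles stripped of journal and
#'   year (default `TRUE`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(rater_id, labels, blinded = TRUE) {
  assert_flag(blinded, "blinded")
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stopf("labels must be named by title id")
  }
  if (anyNA(labels)) stopf("labels contain missing values")
  lab <- as.logical(labels)
  names(lab) <- names(labels)
  structure(
    list(rater_id = as.character(rater_id), labels = lab,
         blinded = blinded),
    class = "annotation_set"
  )
}

#' Cohen's kappa between two raters
#'
#' Observed agreement `po` is the fraction of identically labelled
#' titles; chance agreement `pe` is the sum over classes of the product
#' of the raters' marginal label frequencies; kappa is
#' `(po - pe) / (1 - pe)`. When both raters are constant with identical
#' marginals (`pe = 1`) kappa is undefined and reported as such rather
#' than propagating NaN.
#'
#' @param a,b [annotation_set()] objects over identical title-id sets.
#' @return An object of class `kappa_result`: list with `po`, `pe`,
#'   `kappa`, `n`, `undefined`.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  ids <- names(a$labels)
  if (!setequal(ids, names(b$labels))) {
    stopf("raters annotated different title sets")
  }
  la <- a$labels
  lb <- b$labels[ids]
  n <- length(ids)
  if (n == 0L) stopf("empty annotation sets")
  po <- mean(la == lb)
  pe <- mean(la) * mean(lb) + mean(!la) * mean(!lb)
  undefined <- pe >= 1 - 1e-15
  structure(
    list(
      po = po, pe = pe,
      kappa = if (undefined) NA_real_ else (po - pe) / (1 - pe),
      n = n, undefined = undefined
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Cohen's kappa undefined (pe = 1) on n = %d titles\n", x$n))
  } else {
    cat(sprintf("Cohen's kappa = %.3f (po = %.3f, pe = %.3f, n = %d)\n",
                x$kappa, x$po, x$pe, x$n))
  }
  invisible(x)
}

#' Adjudicate two annotation sets with a tie-breaking rater
#'
#' Titles on which the raters agree pass through; disagreements take the
#' tie-breaker's label. The tie-break set must cover exactly the
#' disagreement set: a missing disagreed title and a tie-break vote on an
#' agreed title are both errors.
#'
#' @param a,b [annotation_set()] objects over identical title-id sets.
#' @param tiebreak named logical vector (or `annotation_set`) over
#'   exactly the disagreed title ids.
#' @return A [tibble::tibble] with columns `title_id`, `label`,
#'   `provenance` (`"agreed"` or `"adjudicated"`), in `a`'s title order.
#' @export
adjudicate <- function(a, b, tiebreak) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  if (inherits(tiebreak, "annotation_set")) tiebreak <- tiebreak$labels
  ids <- names(a$labels)
  if (!setequal(ids, names(b$labels))) {
    stopf("raters annotated different title sets")
  }
  lb <- b$labels[ids]
  disagreed <- ids[a$labels != lb]
  extra <- setdiff(names(tiebreak), disagreed)
  missing <- setdiff(disagreed, names(tiebreak))
  if (length(extra)) {
    stopf("tie-break labels supplied for agreed titles: %s",
          paste(extra, collapse = ", "))
  }
  if (length(missing)) {
    stopf("tie-break labels missing for disagreed titles: %s",
          paste(missing, collapse = ", "))
  }
  label <- a$labels
  label[disagreed] <- as.logical(tiebreak[disagreed])
  tibble::tibble(
    title_id = ids,
    label = as.logical(label),
    provenance = ifelse(ids %in% disagreed, "adjudicated", "agreed")
  )
}

#' Two-proportion z test (no continuity correction)
#'
#' Tests the difference between an early-era and a late-era proportion
#' with the pooled-variance z statistic:
#' `z = (p_late - p_early) / sqrt(pooled * (1 - pooled) * (1/n_early + 1/n_late))`,
#' two-sided p-value `2 * Phi(-|z|)`. The 95% CI for the difference uses
#' the unpooled standard error (Wald); per-era Wilson intervals are
#' included for display. A pooled proportion of exactly 0 or 1 is
#' degenerate: z is undefined and the p-value reported as 1.
#'
#' @param x_early,n_early,x_late,n_late integer counts, `0 <= x <= n`,
#'   `n >= 1`.
#' @return An object of class `prop_comparison`: list with the counts,
#'   `p_early`, `p_late`, `pooled_p`, `z`, `p_value`, `ci_diff`,
#'   `ci_early`, `ci_late`, `degenerate`.
#' @examples
#' two_proportion_z(10, 100, 30, 100)
#' @export
two_proportion_z <- function(x_early, n_early, x_late, n_late) {
  n_early <- assert_count(n_early, "n_early")
  n_late <- assert_count(n_late, "n_late")
  x_early <- assert_count(x_early, "x_early", min = 0L)
  x_late <- assert_count(x_late, "x_late", min = 0L)
  if (x_early > n_early || x_late > n_late) stopf("x exceeds n")

  p1 <- x_early / n_early
  p2 <- x_late / n_late
  pooled <- (x_early + x_late) / (n_early + n_late)
  degenerate <- pooled %in% c(0, 1)
  if (degenerate) {
    z <- NA_real_; pv <- 1
  } else {
    z <- (p2 - p1) /
      sqrt(pooled * (1 - pooled) * (1 / n_early + 1 / n_late))
    pv <- 2 * pnorm(-abs(z))
  }
  se_unpooled <- sqrt(p1 * (1 - p1) / n_early + p2 * (1 - p2) / n_late)
  structure(
    list(
      x_early = x_early, n_early = n_early,
      x_late = x_late, n_late = n_late,
      p_early = p1, p_late = p2, pooled_p = pooled,
      z = z, p_value = pv,
      ci_diff = (p2 - p1) + c(-1, 1) * qnorm(0.975) * se_unpooled,
      ci_early = wilson_ci(x_early, n_early),
      ci_late = wilson_ci(x_late, n_late),
      degenerate = degenerate
    ),
    class = "prop_comparison"
  )
}

# Wilson score interval, used for per-era display CIs.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat(sprintf(
    "two-proportion z: %.3f (%d/%d) vs %.3f (%d/%d), z = %s, p = %.3g\n",
    x$p_early, x$x_early, x$n_early, x$p_late, x$x_late, x$n_late,
    if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z), x$p_value
  ))
  invisible(x)
}

#' Early-vs-late title-length contrast
#'
#' Compares mean title length in characters (Unicode code points,
#' whitespace and the trailing period included) between two eras with
#' Welch's unequal-variance two-sided t test. Identical zero-variance
#' samples short-circuit to `p = 1` (difference 0) rather than failing
#' the degenerate t test.
#'
#' @param early_titles,late_titles non-empty character vectors.
#' @return An object of class `length_comparison`: list with
#'   `mean_early`, `mean_late`, `diff` (late minus early), `p_value`,
#'   `n_early`, `n_late`.
#' @export
title_length_contrast <- function(early_titles, late_titles) {
  if (length(early_titles) == 0L || length(late_titles) == 0L) {
    stopf("both eras must have at least one title")
  }
  le <- nchar(early_titles, type = "chars")
  ll <- nchar(late_titles, type = "chars")
  d <- mean(ll) - mean(le)
  # degenerate inputs (constant lengths, single-title eras) cannot carry a
  # Welch test: equal means report p = 1, otherwise NA
  pv <- tryCatch(
    t.test(ll, le, var.equal = FALSE)$p.value,
    error = function(e) if (d == 0) 1 else NA_real_
  )
  structure(
    list(mean_early = mean(le), mean_late = mean(ll), diff = d,
         p_value = pv, n_early = length(le), n_late = length(ll)),
    class = "length_comparison"
  )
}
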