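---
title: "Methods: diachronic title-language trends and patient-centric classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diachronic title-language trends and patient-centric classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titletrends)
```

## The problem

Article titles are a compact record of what authors and editors consider
the most important elements of a piece of clinical research. Systematic
shifts in title vocabulary over decades — from case-report language
toward trial and risk language, from "diabetic patients" toward
"patients with diabetes" — can be quantified by treating each year of a
journal's output as a bag of title words and asking which words' usage
rates changed linearly over the study period.

`titletrends` implements that analysis as a reusable pipeline over
MEDLINE/PubMed XML: record parsing and cohort filtering, per-year
monogram/bigram frequency tables, a mass-univariate linear trend screen
under false-discovery-rate control, and a rule-based classification of
clinical-trial titles as patient-centric or not, with dual-rater
agreement and early-versus-late era contrasts. A synthetic corpus
generator with known ground truth backs every stage with testable
expectations.

## The trend model

For a term $t$ (a single word, or an adjacent word pair within one
title) with count $c_{t,y}$ in year $y$ and $N_y$ total title tokens
that year, the frequency is

$$f_{t,y} = 10^5 \cdot c_{t,y} / N_y$$

in occurrences per 100,000 title words. The screen fits ordinary least
squares of $f_{t,y}$ on calendar year,

$$f_{t,y} = \alpha + \beta\, y + \varepsilon_y,$$

and tests $\beta = 0$ with the two-tailed $t$ test on $n-2$ degrees of
freedom, where $n$ is the number of years with a nonzero token
denominator. P-values are adjusted by the Benjamini–Hochberg step-up
procedure within each n-gram family, and terms with adjusted $q$ below
the FDR threshold (0.01 by default) are called significant. The slope
$\beta$ is the mean annual change in frequency; $\beta$ times the year
span is the total change over the period, which is also the word-cloud
weight exported for significant terms.

Design choices worth making explicit:

* **One denominator for both orders.** $N_y$ counts all tokens before
  stop-word removal and is shared by the monogram and bigram tables, so
  slopes are on a common per-100,000-words scale. Stop words are removed
  before monogram counting only; they stay in bigrams, where pairs such
  as "patients with" carry the signal of interest.
* **Low-frequency exclusion is an aggregate-period criterion.** A term
  is excluded when its pooled count over the whole period, divided by
  the pooled token total, is strictly below 0.01% (1e-4). The plausible
  alternative (mean of yearly frequencies) is not the default because a
  whole-period reading treats sparse early years and dense late years
  symmetrically; the threshold is a plain argument, so sensitivity
  analyses are one call away.
* **Unweighted OLS.** Yearly token totals vary, so frequency variances
  are heteroscedastic; the model is nevertheless fitted unweighted,
  matching the plain linear-model formulation the screen implements.
  The calibration results below quantify the cost: CI coverage dips
  roughly one to three points below nominal for the steepest injected
  slopes but stays well inside the 90–99% acceptance band.
* **Separate FDR families.** Monograms and bigrams are analysed and
  ranked as separate families, so BH correction is applied within each
  table; callers wanting a joint correction can pool p-values and call
  `bh_adjust()` themselves.
* **Degenerate fits.** A residual sum of squares at numerical zero gets
  the convention $p = 0$ for a nonzero slope and $p = 1$ for a zero
  slope, with a point CI; years with a zero denominator are dropped from
  every series (0/0 is undefined, and imputing zero frequency would
  fabricate a trend) and reported.
* **Rankings are deterministic**: ties in slope break lexicographically.

## Tokenization

Tokens are maximal runs of letters and digits; internal hyphens and
apostrophes are retained ("high-dose", "crohn's"), dash variants are
normalised to plain hyphens beforehand, and every other character
separates. Digits and single-letter tokens are kept so "type 1"
survives. Hyphenated compounds are *not* split — whether a framework
splits "physician-patient" changes bigram counts, so the choice is fixed
here and documented as a sensitivity knob. The stop-word list is a
fixed, versioned 174-word English function-word list shipped with the
package; its version tag travels with every frequency table.

## Patient-centric classification

A title is patient-centric when it contains a noun referring to the
patient or study population that is independent of a disease label. The
default rule set ships two lexicons (patient nouns such as *patients*,
*adults*, *children*; disease adjectives such as *diabetic*,
*asthmatic*) and one structural rule: a patient noun immediately
premodified by a disease adjective ("diabetic patients") does not
qualify. So "insulin therapy for diabetic ketoacidosis" is not
patient-centric (no patient noun), "outcomes in diabetic patients" is
not (the only patient noun is disease-bound), and "outcomes in patients
with diabetes" is. Every output row carries the rule-set version; the
premodifier rule is a flag, and both lexicons are arguments, so
alternative operationalisations remain comparable. The shipped lexicons
are a reproducible stand-in for a manual annotation protocol — they make
no claim to reproduce any particular human raters' agreement level or
proportions.

Dual-rater workflows are supported directly: `cohens_kappa()` computes
observed agreement, chance agreement from the raters' marginals, and
$\kappa = (p_o - p_e)/(1 - p_e)$, reporting the $p_e = 1$ case as
undefined rather than NaN; `adjudicate()` applies a tie-breaking rater
to exactly the disagreement set and records per-title provenance.

Era contrasts use the two-proportion $z$ test with pooled variance and
no continuity correction (its square equals the uncorrected chi-square
statistic on the 2×2 table); the CI for the difference uses the
unpooled standard error, with Wilson intervals per era for display.
Title length is compared in Unicode code points (spaces and trailing
period included) with Welch's unequal-variance $t$ test — the
conservative default when no test is otherwise dictated.

## The synthetic-data generator

`synthetic_spec()` defines a corpus in which every downstream
expectation is known: per-year article counts; title lengths uniform on
4–14 tokens; a vocabulary of injected terms whose per-100,000-words
frequency at year $y$ is $b_t + s_t (y - y_0)$; injected adjacent word
pairs with their own linear rates; a publication-type mix; and two era
windows whose clinical-trial titles are generated from patient-centric
or non-patient-centric templates with era-specific fractions.

Mechanics that matter for interpretation:

* Token-level titles are built by sampling each token slot from the
  year's term distribution. Residual probability mass falls on a filler
  vocabulary disjoint from all injected terms and lexicons, so injected
  frequencies are exact targets, not renormalised approximations.
  Infeasible targets (negative frequency in any year) fail at
  specification time.
* Injected word pairs are overwritten onto random adjacent slots at
  per-year Poisson rates. This perturbs monogram counts by a small
  amount (pairs replace filler tokens); the trend-screen calibration
  therefore uses specs where the monogram and bigram arms are exercised
  separately.
* Trend injection is linear on the frequency scale, not log-frequency,
  matching the model the screen fits.
* `simulate_term_counts()` is the frequency-scale path: it draws each
  year's counts from one multinomial over the same term probabilities,
  skipping title assembly. Marginally per term-year this is the same
  distribution as token-level generation followed by counting (a
  property the test suite checks at desk scale), and it is what the
  calibration studies use at realistic token volumes.
* Default scale: 40 years (1976–2015) at 1,257 articles/year, the
  output volume of one large general-medicine journal; era fractions
  0.25 (early) and 0.55 (late), consistent with absolute increases of
  twenty-odd percentage points in patient-centric titling.
* Everything is driven by one mandatory seed, with integer-based
  sampling paths only, and the generator restores the caller's RNG
  state.

What the generator does **not** emulate: real English syntax outside
the trial templates (token-sampled titles are exchangeable bags of
words), journal-specific style, correlated term usage within titles,
secular changes in title length for the non-template arm, and
nomenclature shifts that are not linear in time. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the stated generative model — not that any particular
real-corpus finding is reproduced.

## Calibration, at the sizes the package tests itself

The acceptance suite (also re-run by `scripts/acceptance.R`) checks, at
the following problem sizes:

* **Slope recovery** — injected slopes of 1, 5 and 10 per 100,000
  words/year, 40 years, 50,000 tokens/year, 200 replicates: the 95% CI
  must cover the true slope in 90–99% of replicates.
* **FDR control** — 1,000 null and 50 trending terms (slope +2, a
  comfortably detectable effect at this scale), 50 replicates: the mean
  realized false-discovery proportion among $q < 0.01$ calls must be at
  most 0.03.
* **Type-I error** — 50 null terms, 100 replicates: the raw
  $p < 0.05$ rate must lie in 3–7%.
* **Oracles** — the OLS path against an independent numerical SSE
  minimiser on random series (1e-8), BH against the textbook step-up
  definition, $\kappa$ and $z$ against hand-computed tables, counting
  against a naive per-title recount, XML writing against field-equal
  re-parsing, and template titles against ground-truth labels (≥ 99%
  concordance).

## Known limitations

* The classifier is a lexicon-plus-one-rule system; titles that are
  patient-centric through rarer nouns or disqualified through rarer
  disease adjectives than the shipped lexicons cover will be
  mislabelled. The lexicons are deliberately small and versioned rather
  than exhaustive.
* The trend model is strictly linear; step changes (an editorial policy
  taking effect in one year) load onto the slope and are not separated
  from gradual drift. Nonlinear and segmented models are out of scope.
* Unweighted OLS on binomial-noise frequencies is mildly anticonservative
  for strongly trending, high-frequency terms (see the coverage numbers
  above); a weighted fit is the natural extension point.
* Live PubMed fetching is out of scope; the package starts from XML on
  disk.
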