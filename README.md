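# titletrends

Diachronic analysis of medical-journal article titles: which words and
word pairs rose or fell over decades, and whether clinical-trial titles
became more patient-centric.

The package is aimed at bibliometrics and medical-humanities
researchers who have (or can simulate) MEDLINE/PubMed records and want
a tested, reproducible pipeline rather than ad-hoc scripts. It covers:

* **MEDLINE I/O** — parse `PubmedArticleSet` XML into validated records
  (title, journal, year, publication types) with a skip-and-tally parse
  report, journal/year cohort filters, and publication-type selection of
  clinical-trial reports (include: clinical trial of any phase,
  randomized, pragmatic, controlled; exclude: comments, editorials,
  letters, reviews, case reports, and other secondary types).
* **N-gram frequency tables** — per-year monogram and bigram counts
  over title tokens, normalised per 100,000 words with a shared
  denominator, a versioned 174-word stop-word list (monograms only),
  and the <0.01% aggregate low-frequency exclusion.
* **Trend screen** — for each retained term, OLS of yearly frequency
  f_ty = 100000·c_ty/N_y on calendar year; the slope β is the mean
  annual frequency change per 100,000 words, tested two-tailed on
  t = β/se with n−2 df, Benjamini–Hochberg adjusted within the n-gram
  family, significant at q < 0.01; top-k increased/decreased rankings
  and |β|·span word-cloud weights.
* **Patient-centric classification** — a versioned rule set (patient
  noun present and not premodified by a disease adjective: "patients
  with diabetes" yes, "diabetic ketoacidosis" no), dual-rater Cohen's κ
  with tie-break adjudication, two-proportion z contrast (no continuity
  correction) and Welch title-length contrast between eras.
* **Synthetic corpora** — MEDLINE-style XML with known injected linear
  trends, publication-type mixes and template patient-centric titles,
  so every stage is validated against ground truth.
* **Pipeline** — `run_pipeline()` wires
  simulate → parse → count → trend → classify → contrast → report from
  one YAML config, with a run manifest (config hash, versions, seeds,
  file digests). A thin CLI wrapper ships at `inst/cli/titletrends.R`.

## Worked example

Generate a 40-year synthetic corpus with known trends, screen bigrams,
and contrast patient-centric titling between eras:

```r
library(titletrends)

spec <- synthetic_spec(years = 1976:2015, articles_per_year = 300, seed = 2024)
gen  <- generate_corpus(spec)

tab <- build_frequency_table(gen$records, order = 2L)
scr <- screen(tab, fdr_threshold = 0.01, k = 5)
scr
#> <screen_report> 87 terms screened, 4 significant at FDR < 0.01
#> top increased: patients with, in patients, association between
#> top decreased: caused by

scr$top_increased[, c("term", "slope", "ci_low", "ci_high", "q")]
#>                  term slope ci_low ci_high        q
#> 1       patients with 11.03   7.92   14.15 1.23e-06
#> 2         in patients  7.84   5.33   10.36 9.42e-06
#> 3 association between  2.94   1.50    4.37 3.98e-03
```

The slope is the mean annual frequency change per 100,000 title words:
"patients with" rises by about 11 occurrences per 100,000 words per
year (the generator injected 11.37), and its 95% CI covers the truth.
Word-cloud weights are the absolute total change over the 39-year span:

```r
head(sort(cloud_weights(scr, year_span = 39), decreasing = TRUE), 3)
#> patients with   in patients     caused by
#>         430.3         305.9         119.4
```

Classify the clinical-trial titles and contrast the eras:

```r
trials <- select_clinical_trials(gen$records)
lab    <- classify_title(trials$title)
early  <- trials$year <= 1980; late <- trials$year >= 2011
two_proportion_z(sum(lab$patient_centric[early]), sum(early),
                 sum(lab$patient_centric[late]),  sum(late))
#> two-proportion z: 0.249 (56/225) vs 0.521 (113/217), z = 5.879, p = 4.12e-09
```

The generator's era fractions were 0.25 and 0.55; the rule-based
classifier recovers the ~28-point increase and the z test flags it.

Or run everything from a config:

```r
run_pipeline(list(seed = 19,
                  synthetic = list(years = c(1976, 2015))),
             out_dir = "out/")
```

which writes `records.tsv`, `monograms.tsv`/`bigrams.tsv`, per-family
screen TSVs and top-k JSON, `labels.tsv`, `contrast.json`,
`report.json` and `manifest.json`.

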