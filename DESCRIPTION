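Package: titletrends
Title: Diachronic Word-Frequency Trends and Patient-Centric Language in
    Medical Journal Article Titles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining MEDLINE/PubMed article titles for changes in
    language over time. Parses PubmedArticleSet XML into validated records,
    builds per-year monogram and bigram frequency tables normalised per
    100,000 title words, screens every retained term with a continuous
    linear model of frequency on publication year under Benjamini-Hochberg
    false discovery rate control, and classifies clinical-trial titles as
    patient-centric or not under a versioned rule set with dual-rater
    agreement (Cohen's kappa), adjudication, and early-versus-late era
    contrasts (two-proportion z test, Welch title-length test). A synthetic
    corpus generator with known injected trends and template titles
    provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
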