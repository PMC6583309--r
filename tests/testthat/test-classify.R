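test_that("representative titles classify per the patient-noun rule", {
  cls <- classify_title(c(
    paste("Effect of aliskiren on progression of coronary disease in",
          "patients with prehypertension: the AQUARIUS randomized",
          "clinical trial"),
    "Prazosin and clonidine for moderately severe hypertension",
    "Low- and high-dose intravenous insulin therapy for diabetic ketoacidosis"
  ))
  expect_equal(cls$patient_centric, c(TRUE, FALSE, FALSE))
  expect_equal(cls$evidence[[1]], "patients")
  expect_equal(cls$evidence[[2]], character(0))
})

test_that("the independence rule disqualifies disease-premodified nouns", {
  cls <- classify_title(c(
    "Outcomes in diabetic patients treated with insulin",
    "Outcomes in patients with diabetes treated with insulin"
  ))
  expect_equal(cls$patient_centric, c(FALSE, TRUE))
  expect_equal(cls$disqualified[[1]], "diabetic patients")

  # the rule is configurable
  rules_off <- rule_set(independence_rule = FALSE)
  cls2 <- classify_title("Outcomes in diabetic patients", rules_off)
  expect_true(cls2$patient_centric)
})

test_that("classification is invariant to case and surrounding punctuation", {
  variants <- c(
    "TRIAL OF X IN PATIENTS WITH Y",
    "Trial of x in patients, with y.",
    "Trial of x (in patients) with y"
  )
  cls <- classify_title(variants)
  expect_true(all(cls$patient_centric))
  expect_equal(cls$rules_version, rep(rule_set()$version, 3))
})

test_that("empty rule sets are rejected", {
  expect_error(rule_set(patient_nouns = character(0)), "empty")
})

test_that("kappa matches the hand-computed 2x2 example", {
  ids <- paste0("t", 1:50)
  a <- annotation_set("a", setNames(
    rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 15, 5, 10)), ids))
  b <- annotation_set("b", setNames(
    rep(c(TRUE, FALSE, FALSE, TRUE), c(20, 15, 5, 10)), ids))
  k <- cohens_kappa(a, b)
  expect_equal(k$po, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_equal(k$n, 50L)
})

test_that("identical non-constant labels give kappa 1; constant raters are undefined", {
  ids <- paste0("t", 1:10)
  lab <- setNames(rep(c(TRUE, FALSE), 5), ids)
  expect_equal(cohens_kappa(annotation_set("a", lab),
                            annotation_set("b", lab))$kappa, 1)
  const <- setNames(rep(TRUE, 10), ids)
  k <- cohens_kappa(annotation_set("a", const), annotation_set("b", const))
  expect_true(k$undefined)
  expect_true(is.na(k$kappa))
})

test_that("kappa concentrates near zero for an independent rater and grows with agreement", {
  set.seed(314)
  ids <- paste0("t", 1:10000)
  a <- annotation_set("a", setNames(runif(10000) < 0.4, ids))
  b <- annotation_set("b", setNames(runif(10000) < 0.5, ids))
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.05)

  agree_seq <- c(0.6, 0.8, 0.95)
  kappas <- vapply(agree_seq, function(pa) {
    keep <- runif(10000) < pa
    lb <- ifelse(keep, a$labels, runif(10000) < 0.5)
    cohens_kappa(a, annotation_set("b", setNames(lb, ids)))$kappa
  }, numeric(1))
  expect_true(all(diff(kappas) > 0))
})

test_that("adjudication passes agreements through and tie-breaks the rest", {
  ids <- paste0("t", 1:4)
  a <- annotation_set("a", setNames(c(TRUE, TRUE, FALSE, FALSE), ids))
  b <- annotation_set("b", setNames(c(TRUE, FALSE, FALSE, TRUE), ids))

  out <- adjudicate(a, b, setNames(c(TRUE, FALSE), c("t2", "t4")))
  expect_equal(out$label, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$provenance, c("agreed", "adjudicated", "agreed",
                                 "adjudicated"))

  # no disagreements: everything agreed, tiebreak empty
  out2 <- adjudicate(a, a, setNames(logical(0), character(0)))
  expect_equal(out2$label, unname(a$labels))
  expect_true(all(out2$provenance == "agreed"))

  # over- and under-coverage are errors
  expect_error(adjudicate(a, b, setNames(TRUE, "t1")), "agreed titles")
  expect_error(adjudicate(a, b, setNames(TRUE, "t2")), "missing")
})

test_that("the two-proportion z test matches its hand oracle and chi-square", {
  pc <- two_proportion_z(10, 100, 30, 100)
  # pooled p = 0.2; z = 0.2 / sqrt(0.2*0.8*0.02)
  expect_equal(pc$pooled_p, 0.2)
  expect_equal(pc$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(pc$z, 3.5355339, tolerance = 1e-6)
  expect_equal(pc$p_value, 2 * pnorm(-abs(pc$z)), tolerance = 1e-12)

  # z^2 equals the uncorrected chi-square statistic
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.5)
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    pz <- two_proportion_z(x1, n1, x2, n2)
    chi <- chisq.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2),
                      correct = FALSE)
    expect_equal(pz$z^2, unname(chi$statistic), tolerance = 1e-8)
    expect_equal(pz$p_value, chi$p.value, tolerance = 1e-8)
  }
})

test_that("the z test handles null, swapped and degenerate inputs", {
  eq <- two_proportion_z(20, 100, 20, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  ab <- two_proportion_z(10, 100, 30, 100)
  ba <- two_proportion_z(30, 100, 10, 100)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)

  dg <- two_proportion_z(0, 50, 0, 80)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("title-length contrast counts characters and tests the shift", {
  lc <- title_length_contrast("ab", "abcd")
  expect_equal(lc$mean_early, 2)
  expect_equal(lc$mean_late, 4)
  expect_equal(lc$diff, 2)

  same <- title_length_contrast(c("abc", "de"), c("abc", "de"))
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  # +40-character mean offset recovered at n = 500/era
  set.seed(7)
  mk <- function(n, mu) vapply(pmax(5, round(rnorm(n, mu, 15))),
                               function(k) strrep("x", k), character(1))
  lc2 <- title_length_contrast(mk(500, 60), mk(500, 100))
  expect_lt(abs(lc2$diff - 40), 5)
  expect_lt(lc2$p_value, 1e-6)
})
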