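make_terms <- function(beta_iv, se_iv = 0, pki = 2, pki_is_default = FALSE,
                       ki_se_M = 0, de = 1, action = "agonist",
                       drug = "clozapine", side_effect = "weight_gain",
                       receptor = paste0("R", seq_along(beta_iv))) {
  terms <- data.frame(
    drug = drug, side_effect = side_effect, receptor = receptor,
    beta_iv = beta_iv, se_iv = se_iv, pki = pki,
    is_default = pki_is_default,
    ki_mean_M = ifelse(pki_is_default, NA_real_, 10^(-(pki + 4))),
    ki_se_M = ki_se_M, de = de, action = action,
    stringsAsFactors = FALSE)
  terms$direction <- suppressWarnings(direction_for_action(terms$action))
  terms$a_d <- dose_adjustment(terms$pki, terms$de)
  terms$signed_value <- terms$direction * terms$beta_iv *
    (terms$pki + terms$a_d)
  terms
}

test_that("signed term composes beta_IV, pKi, dose adjustment and action direction", {
  expect_equal(signed_term(1, 1, 1, "agonist")$signed_value, 1)
  expect_equal(signed_term(0.5, 2, 10, "agonist")$signed_value, 2)
  expect_equal(signed_term(0.5, 2, 10, "antagonist")$signed_value, -2)
  expect_equal(signed_term(0.5, 2, 10, "inverse_agonist")$signed_value, -2)
  expect_warning(st <- signed_term(1, 2, 1, "partial_agonist"),
                 "partial agonist")
  expect_equal(st$direction, 1)
  expect_equal(signed_term(1, 2, 1, "positive_modulator")$direction, 1)
  st <- signed_term(0.5, 2, 0.1, "agonist")
  expect_equal(st$a_d, -2)
  expect_equal(st$signed_value, 0)  # pKi + a_d vanishes when log10(de) = -1
})

test_that("side-effect entries sum signed and absolute term values", {
  terms <- make_terms(c(1, -0.25), pki = 2, de = 1)  # signed 2.0, -0.5
  entry <- score_side_effect(terms)
  expect_equal(entry$score, 1.5)
  expect_equal(entry$abs_score, 2.5)
  expect_false(entry$no_evidence)
  one <- make_terms(0.7)
  expect_equal(score_side_effect(one)$score, one$signed_value)
  empty <- score_side_effect(NULL)
  expect_equal(empty$score, 0)
  expect_true(empty$no_evidence)
  set.seed(41)
  for (k in 1:20) {
    terms <- make_terms(rnorm(sample(1:8, 1)), pki = runif(1, 0.5, 4),
                        de = runif(1, 0.5, 2),
                        action = sample(c("agonist", "antagonist"), 1))
    e <- score_side_effect(terms)
    expect_equal(e$score, sum(terms$signed_value), tolerance = 1e-12)
    expect_equal(e$abs_score, sum(abs(terms$signed_value)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap SE is zero for degenerate inputs and deterministic by seed", {
  terms <- make_terms(1, se_iv = 0, pki = 2, ki_se_M = 0)
  expect_identical(bootstrap_se(terms, n_boot = 1000, seed = 5), 0)
  terms$se_iv <- 0.1
  a <- bootstrap_se(terms, n_boot = 500, seed = 7)
  b <- bootstrap_se(terms, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_gt(a, 0)
  expect_error(bootstrap_se(terms, n_boot = 1), "n_boot")
})

test_that("bootstrap SE matches closed-form linear propagation", {
  # single term, only beta_IV uncertain: SE(S) = |pKi + a_d| * se_IV
  terms <- make_terms(1, se_iv = 0.1, pki = 2, de = 1)
  se <- bootstrap_se(terms, n_boot = 1000, seed = 11)
  expect_equal(se, 0.2, tolerance = 3 * 0.2 / sqrt(2 * 999))
  # with a non-unit dose equivalent the factor is |pKi (1 + log10 de)|
  terms <- make_terms(1, se_iv = 0.1, pki = 2, de = 10)
  se <- bootstrap_se(terms, n_boot = 1000, seed = 11)
  expect_equal(se, 0.4, tolerance = 3 * 0.4 / sqrt(2 * 999))
  # doubling n_boot leaves the estimate stable
  se2 <- bootstrap_se(terms, n_boot = 2000, seed = 12)
  expect_lt(abs(se2 - se), 5 * 0.4 / sqrt(2 * 999))
})

test_that("drug-level SEs respect shared affinity draws across side-effects", {
  # two side-effects scored through the same default-imputed receptor:
  # their replicates share the pKi draw, so the drug-level SD is the sum
  # of the entry SDs (perfect correlation), not their quadrature sum.
  terms <- rbind(
    make_terms(1, se_iv = 0, pki = 0.824, pki_is_default = TRUE,
               side_effect = "weight_gain", receptor = "GABRA5"),
    make_terms(1, se_iv = 0, pki = 0.824, pki_is_default = TRUE,
               side_effect = "neutropenia", receptor = "GABRA5"))
  boot <- bootstrap_scores(terms, n_boot = 2000, seed = 9)
  expect_equal(boot$drug$se_signed, sum(boot$entry$se_signed),
               tolerance = 0.02)
  expect_gt(boot$drug$se_signed, 1.5 * max(boot$entry$se_signed))
})

test_that("aggregation conserves mass and classifies on-target dominance", {
  cfg <- default_config()
  set.seed(42)
  terms <- rbind(
    make_terms(c(0.5, -0.2), pki = 2, receptor = c("DRD2", "HRH1"),
               side_effect = "weight_gain"),
    make_terms(0.3, pki = 1.5, receptor = "HTR6",
               side_effect = "neutropenia"),
    make_terms(c(0.4, 0.1), pki = 3, receptor = c("HTR2A", "ADRB1"),
               side_effect = "sedation", drug = "olanzapine"))
  agg <- aggregate_scores(terms, cfg)
  total <- sum(abs(terms$signed_value))
  expect_equal(sum(agg$drug_scores$abs_score), total, tolerance = 1e-9)
  expect_equal(sum(agg$receptor_summary$abs_score), total, tolerance = 1e-9)
  expect_equal(sum(agg$side_effect_summary$abs_score), total,
               tolerance = 1e-9)
  # weight_gain: DRD2 (on-target) contributes 1.0 of 1.4 -> on-target
  wg <- agg$classification[agg$classification$side_effect == "weight_gain", ]
  expect_equal(wg$on_target_fraction, 1 / 1.4, tolerance = 1e-12)
  expect_equal(wg$dominated_by, "on_target")
  ne <- agg$classification[agg$classification$side_effect == "neutropenia", ]
  expect_equal(ne$dominated_by, "off_target")
  # brute-force group-by-sum oracle for the drug totals
  want <- tapply(abs(terms$signed_value), terms$drug, sum)
  expect_equal(agg$drug_scores$abs_score,
               as.numeric(want[agg$drug_scores$drug]), tolerance = 1e-12)
  # signed totals too
  want_s <- tapply(terms$signed_value, terms$drug, sum)
  expect_equal(agg$drug_scores$score,
               as.numeric(want_s[agg$drug_scores$drug]), tolerance = 1e-12)
})

test_that("scores scale linearly in beta_IV and ignore a_d at unit dose", {
  terms <- make_terms(c(0.5, -0.2, 0.1), pki = c(1, 2, 3), de = 1)
  expect_equal(terms$a_d, c(0, 0, 0))
  scaled <- make_terms(2 * c(0.5, -0.2, 0.1), pki = c(1, 2, 3), de = 1)
  expect_equal(score_side_effect(scaled)$score,
               2 * score_side_effect(terms)$score, tolerance = 1e-12)
  # de = 1 makes the score equal to the dose-free composition
  expect_equal(terms$signed_value, terms$beta_iv * terms$pki,
               tolerance = 1e-12)
})
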