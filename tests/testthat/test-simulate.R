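test_that("locus simulation is deterministic and leaves the caller's RNG alone", {
  a <- simulate_locus_pair("H4", m_snps = 20, seed = 99)
  b <- simulate_locus_pair("H4", m_snps = 20, seed = 99)
  expect_identical(a, b)
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_locus_pair("H1", m_snps = 5, seed = 3))
  expect_identical(runif(1), before)
  expect_error(simulate_locus_pair("H4", maf = 0.6), "maf")
  expect_error(simulate_locus_pair("H3", m_snps = 10,
                                   causal_index = 4, causal_index2 = 4),
               "distinct")
})

test_that("causal configurations place effects where the scenario says", {
  h3 <- simulate_locus_pair("H3", m_snps = 30, seed = 5)
  expect_false(h3$causal_index_exposure == h3$causal_index_outcome)
  h4 <- simulate_locus_pair("H4", m_snps = 30, seed = 5)
  expect_equal(h4$causal_index_exposure, h4$causal_index_outcome)
  h0 <- simulate_locus_pair("H0", m_snps = 30, seed = 5)
  expect_true(is.na(h0$causal_index_exposure))
  # H4 at benchmark settings: both traits strongly associated at the SNP
  z1 <- h4$eqtl$beta / h4$eqtl$se
  expect_gt(abs(z1[h4$causal_index_exposure]), 20)
})

test_that("null loci show no genome-wide-scale signal", {
  n_quiet <- 0
  for (s in 1:100) {
    sim <- simulate_locus_pair("H0", m_snps = 30, seed = s)
    zmax <- max(abs(c(sim$eqtl$beta / sim$eqtl$se,
                      sim$gwas$beta / sim$gwas$se)))
    n_quiet <- n_quiet + (zmax < 5.45)
  }
  expect_gte(n_quiet, 95)
})

test_that("empirical spread of simulated estimates matches the analytic SE", {
  maf <- 0.3; n <- 50000
  se_analytic <- 1 / sqrt(2 * maf * (1 - maf) * n)
  draws <- vapply(1:1000, function(s) {
    simulate_locus_pair("H0", m_snps = 3, maf = maf, n_gwas = n,
                        seed = s)$gwas$beta[2]
  }, numeric(1))
  expect_lt(abs(sd(draws) / se_analytic - 1), 0.1)
})

test_that("simulated affinity tables exercise every summarization path", {
  # no noise, no outliers: the trimmed mean recovers the true Ki exactly
  clean <- simulate_affinity_table("d1", c("R1", "R2"), noise_sd_log10 = 0,
                                   outlier_rate = 0, missing_rate = 0,
                                   seed = 4)
  for (r in c("R1", "R2")) {
    vals <- clean$rows$ki_nM[clean$rows$receptor == r]
    truth <- clean$truth$true_ki_nM[clean$truth$receptor == r]
    expect_equal(trimmed_mean(vals, 0.1)$mean, truth, tolerance = 1e-12)
  }
  # missing_rate 1: every pair is a blank row driving default imputation
  missing <- simulate_affinity_table("d1", c("R1", "R2"), missing_rate = 1,
                                     seed = 4)
  expect_true(all(is.na(missing$rows$ki_nM)))
  summ <- summarize_affinity_table(missing$rows)
  expect_true(all(summ$is_default))
  expect_true(all(summ$pki == 0.824))
  # outliers: trimming beats the untrimmed mean on the log-Ki error
  # (measurement counts >= 10 so the 0.1 proportion trims at least one
  # value from each tail)
  truth_df <- data.frame(drug = "d1", receptor = "R1", true_ki_nM = 5,
                         action = "antagonist", stringsAsFactors = FALSE)
  err_t <- err_u <- numeric(100)
  for (s in 1:100) {
    sim <- simulate_affinity_table("d1", "R1", truth = truth_df,
                                   noise_sd_log10 = 0.1,
                                   outlier_rate = 0.2, missing_rate = 0,
                                   n_measurements = 12:20, seed = s)
    vals <- sim$rows$ki_nM
    err_t[s] <- abs(log10(trimmed_mean(vals, 0.1)$mean) - log10(5))
    err_u[s] <- abs(log10(mean(vals)) - log10(5))
  }
  expect_lt(mean(err_t), mean(err_u))
})

test_that("study bundles are self-consistent, labelled, and reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  study <- small_study()
  b1 <- simulate_study(study, seed = 77, out_dir = dir1)
  b2 <- simulate_study(study, seed = 77, out_dir = dir2)
  expect_identical(b1$truth, b2$truth)
  expect_identical(readLines(b1$paths$eqtl), readLines(b2$paths$eqtl))

  # every generated file passes io validation with zero rejects
  eqtl <- read_sumstats(b1$paths$eqtl, eqtl = TRUE)
  expect_equal(attr(eqtl, "n_rejected"), 0)
  expect_equal(nrow(eqtl),
               nrow(study$genes) * length(study$tissues) * study$m_snps)
  for (p in unique(study$side_effect_map$phenotype_id)) {
    g <- read_sumstats(file.path(b1$paths$gwas_dir, paste0(p, ".tsv")))
    expect_equal(attr(g, "n_rejected"), 0)
  }
  aff <- read_affinity_table(b1$paths$affinity)
  expect_equal(attr(aff, "n_rejected"), 0)
  expect_s3_class(read_side_effect_map(b1$paths$side_effect_map),
                  "data.frame")
  expect_s3_class(read_dose_equivalents(b1$paths$dose_equivalents),
                  "data.frame")

  # truth manifest bookkeeping: planted pairs expand to drugs x pairs triples
  scen <- b1$truth$scenarios
  expect_equal(sum(scen$hypothesis == "H4"), nrow(study$planted))
  expect_equal(sum(scen$hypothesis == "H3"), nrow(study$h3_decoys))
  h3 <- scen[scen$hypothesis == "H3", ]
  expect_true(all(h3$causal_index_exposure != h3$causal_index_outcome))
  expect_equal(nrow(b1$truth$planted_triples),
               nrow(study$planted) * length(study$drugs))
  expect_false(any(duplicated(b1$truth$planted_triples)))
})
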