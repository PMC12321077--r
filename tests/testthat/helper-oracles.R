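# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles deliberately use naive direct-scale /
# enumeration algorithms, not the package's code paths.

# Exhaustive configuration enumeration for two-trait colocalization at
# direct (non-log) scale; valid for moderate |z| only.
enum_coloc_oracle <- function(locus, priors, sd1 = 0.15, sd2 = 0.15) {
  a1 <- exp(log_abf(locus$beta1, locus$se1, sd1))
  a2 <- exp(log_abf(locus$beta2, locus$se2, sd2))
  m <- nrow(locus)
  w3 <- 0; w4 <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) w4 <- w4 + priors$p12 * a1[i] * a2[i]
      else w3 <- w3 + priors$p1 * priors$p2 * a1[i] * a2[j]
    }
  }
  w <- c(1, priors$p1 * sum(a1), priors$p2 * sum(a2), w3, w4)
  stats::setNames(w / sum(w), c("H0", "H1", "H2", "H3", "H4"))
}

# Random locus with bounded z so the direct-scale oracle stays finite:
# the per-SNP ABF product of the two traits must not overflow a double,
# which caps |z| per trait at roughly sqrt(308 * log(10)) ~ 26.
random_locus <- function(m, signal_rate = 0.2) {
  se1 <- stats::runif(m, 0.02, 0.1)
  se2 <- stats::runif(m, 0.02, 0.1)
  spike <- function() {
    ifelse(stats::runif(m) < signal_rate,
           sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, 5, 8), 0)
  }
  z1 <- stats::rnorm(m, 0, 1.5) + spike()
  z2 <- stats::rnorm(m, 0, 1.5) + spike()
  data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
             beta1 = z1 * se1, se1 = se1,
             beta2 = z2 * se2, se2 = se2, stringsAsFactors = FALSE)
}

# Textbook O(n^2) Benjamini-Hochberg step-up.
naive_bh <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    cand <- vapply(seq_len(n), function(j) {
      if (p[j] >= p[i]) n * p[j] / sum(p <= p[j]) else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Group-by-and-argmin oracle for the one-result-per-pair rule.
naive_dedupe <- function(res) {
  out <- list()
  for (s in unique(res$side_effect)) {
    for (g in unique(res$gene)) {
      sub <- res[res$side_effect == s & res$gene == g, , drop = FALSE]
      if (nrow(sub) == 0) next
      sub <- sub[sub$qval == min(sub$qval), , drop = FALSE]
      sub <- sub[sub$f_stat == max(sub$f_stat), , drop = FALSE]
      sub <- sub[order(sub$snp), , drop = FALSE]
      out[[length(out) + 1]] <- sub[1, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$side_effect, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Valid summary-statistics rows for reader tests.
make_sumstats_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%06d", sample.int(1e6, n)),
    chr = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ea = rep_len(c("A", "C", "G", "T"), n),
    oa = rep_len(c("G", "T", "A", "C"), n),
    eaf = round(stats::runif(n, 0.05, 0.95), 6),
    beta = stats::rnorm(n),
    se = stats::runif(n, 0.01, 0.5),
    pval = stats::runif(n, 1e-10, 1),
    n = sample(1000:100000, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# A reduced synthetic study for fast pipeline tests: 3 receptor genes,
# 3 phenotypes, 30-SNP loci, 2 brain tissues + blood.
small_study <- function() {
  study <- default_study_config()
  study$genes <- study$genes[study$genes$gene %in%
                               c("DRD2", "HRH1", "GABRA1"), ]
  study$side_effect_map <- data.frame(
    side_effect = c("weight_gain", "neutropenia", "blood_pressure"),
    phenotype_id = c("pheno_bmi", "pheno_neutrophil_count",
                     "pheno_systolic_bp"),
    brain_relevant = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  study$planted <- data.frame(
    gene = c("DRD2", "GABRA1"),
    phenotype_id = c("pheno_bmi", "pheno_neutrophil_count"),
    stringsAsFactors = FALSE)
  study$h3_decoys <- data.frame(
    gene = "HRH1", phenotype_id = "pheno_systolic_bp",
    stringsAsFactors = FALSE)
  study$tissues <- c("cortex", "cerebellum", "blood")
  study$m_snps <- 30
  study
}

run_small_pipeline <- function(seed, dir) {
  bundle <- simulate_study(small_study(), seed = seed,
                           out_dir = file.path(dir, "bundle"))
  config <- default_config()
  config$paths <- bundle$paths
  config$out_dir <- file.path(dir, "out")
  config$seed <- as.integer(seed)
  config$n_boot <- 200
  res <- suppressMessages(suppressWarnings(run_pipeline(config)))
  list(bundle = bundle, config = config, result = res)
}
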