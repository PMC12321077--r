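test_that("F statistic is the squared t ratio with the weak-instrument cut at 22", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0.01, 0.01), 1)
  expect_equal(f_statistic(0, 0.05), 0)
  expect_error(f_statistic(0.1, 0))
})

test_that("instrument selection takes the lead cis SNP per tissue", {
  genes <- data.frame(gene = "DRD2", chrom = "11", start = 2e6, end = 2.05e6)
  base <- make_sumstats_df(3)
  base$chr <- "11"
  base$pos <- c(2.01e6, 2.02e6, 2.03e6)
  base$pval <- c(1e-8, 1e-5, 0.2)
  base$gene <- "DRD2"
  base$tissue <- "cortex"
  inst <- select_instruments(base, genes)
  expect_equal(nrow(inst), 1)
  expect_equal(inst$snp, base$snp[1])
  expect_equal(inst$f_stat, (base$beta[1] / base$se[1])^2)

  # one top SNP shared by 5 tissues collapses to 5 (gene, tissue) rows
  multi <- do.call(rbind, lapply(
    c("basal_ganglia", "cerebellum", "cortex", "hippocampus", "spinal_cord"),
    function(t) { x <- base; x$tissue <- t; x }))
  inst <- select_instruments(multi, genes)
  expect_equal(nrow(inst), 5)
  expect_equal(length(unique(inst$snp)), 1)

  # cis boundary: just inside kept, one bp beyond the 1 Mb window dropped
  edge <- base[1:2, ]
  edge$pos <- c(2.05e6 + 1e6, 2.05e6 + 1e6 + 1)
  edge$pval <- c(0.5, 1e-10)
  inst <- select_instruments(edge, genes)
  expect_equal(inst$snp, edge$snp[1])
  trans <- base
  trans$chr <- "2"
  expect_message(expect_equal(nrow(select_instruments(trans, genes)), 0),
                 "no cis")
})

test_that("Wald ratio matches hand evaluation and is homogeneous in the outcome", {
  wr <- wald_ratio(0.2, 0.05, 0.1, 0.01)
  expect_equal(wr$beta_iv, 2)
  expect_equal(wr$se_iv, 0.5)
  expect_equal(wr$pval, 2 * pnorm(-4))
  wr0 <- wald_ratio(0, 0.05, 0.1, 0.01)
  expect_equal(wr0$beta_iv, 0)
  expect_equal(wr0$pval, 1)
  expect_equal(wald_ratio(-0.3, 0.1, 0.15, 0.01)$beta_iv, -2)
  expect_error(wald_ratio(0.2, 0.05, 0, 0.01), "undefined ratio")
  # scaling the outcome by k scales beta_iv and se_iv by k
  set.seed(21)
  for (i in 1:20) {
    zy <- rnorm(1); sy <- runif(1, .01, .2)
    zx <- rnorm(1, 0.3, 0.05); sx <- runif(1, .01, .05)
    k <- runif(1, 0.1, 5)
    a <- wald_ratio(zy, sy, zx, sx)
    b <- wald_ratio(k * zy, k * sy, zx, sx)
    expect_equal(b$beta_iv, k * a$beta_iv, tolerance = 1e-12)
    expect_equal(b$se_iv, k * a$se_iv, tolerance = 1e-12)
    expect_equal(b$pval, a$pval, tolerance = 1e-12)
  }
  # second-order SE adds the exposure-uncertainty term
  so <- wald_ratio(0.2, 0.05, 0.1, 0.01, method = "second_order")
  expect_equal(so$se_iv, sqrt(0.05^2 / 0.01 + 0.04 * 1e-4 / 1e-4),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the naive step-up oracle", {
  expect_equal(bh_fdr(0.037), 0.037)                   # single test
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)))
  set.seed(22)
  for (k in 1:200) {
    n <- sample(1:50, 1)
    p <- runif(n)^sample(1:3, 1)
    if (k %% 5 == 0) p[sample(n, 1)] <- p[1]  # exercise ties
    q <- bh_fdr(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("screen crosses instruments with phenotypes and accounts for skips", {
  inst <- data.frame(
    gene = c("DRD2", "HRH1"), tissue = "cortex",
    snp = c("rs1", "rs2"), ea = "A", oa = "G", eaf = 0.3,
    beta = c(0.3, 0.25), se = 0.01, pval = 1e-100, n = 5e4,
    stringsAsFactors = FALSE)
  inst$f_stat <- f_statistic(inst$beta, inst$se)
  gwas <- function(betas, swap = FALSE) {
    data.frame(snp = c("rs1", "rs2"),
               ea = if (swap) "G" else "A", oa = if (swap) "A" else "G",
               eaf = 0.3, beta = betas, se = 0.02, pval = 0.5, n = 1e5,
               stringsAsFactors = FALSE)
  }
  store <- list(ph1 = gwas(c(0.15, 0.1)), ph2 = gwas(c(0, 0.01)),
                ph3 = gwas(c(-0.2, 0.3), swap = TRUE))
  se_map <- data.frame(side_effect = c("se_a", "se_b", "se_c"),
                       phenotype_id = c("ph1", "ph2", "ph3"),
                       brain_relevant = TRUE, stringsAsFactors = FALSE)
  res <- screen(inst, store, se_map)
  expect_equal(attr(res, "n_tested"), 6)      # 2 instruments x 3 phenotypes
  expect_equal(attr(res, "n_skipped"), 0)
  all_res <- attr(res, "all_results")
  # swapped alleles are sign-corrected before the ratio
  r31 <- all_res[all_res$phenotype_id == "ph3" & all_res$snp == "rs1", ]
  expect_equal(r31$beta_zy, 0.2)
  expect_equal(r31$beta_iv, 0.2 / 0.3)
  # a missing outcome record is skipped, with exact accounting
  store$ph2 <- store$ph2[store$ph2$snp != "rs2", ]
  res <- suppressMessages(screen(inst, store, se_map))
  expect_equal(attr(res, "n_skipped"), 1)
  expect_equal(attr(res, "skipped")$reason, "snp_absent")
  expect_equal(attr(res, "n_tested") + attr(res, "n_skipped"),
               attr(res, "n_combinations"))
  # weak instruments are excluded up front
  weak <- inst
  weak$f_stat[1] <- 4
  res <- suppressMessages(screen(weak, store, se_map))
  expect_equal(attr(res, "n_combinations"), 3)
})

test_that("one result per side-effect/receptor pair, deterministic tie-breaks", {
  res <- data.frame(
    side_effect = "weight_gain", gene = "DRD2",
    phenotype_id = c("ph1", "ph2"), snp = c("rs1", "rs2"),
    qval = c(0.001, 0.01), f_stat = c(100, 200), stringsAsFactors = FALSE)
  expect_equal(dedupe_pair_results(res)$qval, 0.001)
  res$qval <- c(0.01, 0.01)
  expect_equal(dedupe_pair_results(res)$f_stat, 200)
  res$f_stat <- c(50, 50)
  expect_equal(dedupe_pair_results(res)$snp, "rs1")

  set.seed(23)
  for (k in 1:100) {
    n <- sample(2:40, 1)
    r <- data.frame(
      side_effect = sample(c("a", "b", "c"), n, replace = TRUE),
      gene = sample(c("G1", "G2"), n, replace = TRUE),
      phenotype_id = sprintf("ph%d", seq_len(n)),
      snp = sprintf("rs%d", sample.int(20, n, replace = TRUE)),
      qval = sample(round(runif(5, 0.001, 0.04), 3), n, replace = TRUE),
      f_stat = sample(c(30, 100, 400), n, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- dedupe_pair_results(r)
    want <- naive_dedupe(r)
    got <- got[order(got$side_effect, got$gene), ]
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})
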