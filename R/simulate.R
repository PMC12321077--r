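## Ground-truth-labelled summary-statistic simulator. Generates complete
## input bundles (eQTL tables, GWAS summary statistics, affinity tables,
## maps, dose equivalents) with the statistical structure the pipeline
## assumes, so every stage and the end-to-end run are testable without
## external downloads. Summary-statistic level only: no individual-level
## genotypes.

.NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

ar1_sigma <- function(m, rho) {
  stopifnot(rho >= 0, rho < 1)
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

## Marginal summary effects at a locus: mean = Sigma %*% causal, noise
## multivariate normal with covariance se^2 * Sigma (the standard
## summary-statistic approximation under LD matrix Sigma).
sim_marginal_stats <- function(sigma_chol, causal, se) {
  m <- length(causal)
  mu <- crossprod(sigma_chol, sigma_chol %*% causal)  # Sigma %*% causal
  as.numeric(mu + se * crossprod(sigma_chol, stats::rnorm(m)))
}

## Locus layout: positions, rsIDs and non-palindromic alleles. Alleles
## are a property of the variant, not of the draw: they are assigned
## deterministically from the position, so independent simulations of
## the same coordinates stay allele-consistent.
locus_layout <- function(m, chrom, start_pos, spacing = 2000) {
  pos <- start_pos + (seq_len(m) - 1L) * spacing
  pair_idx <- ((pos %/% spacing) + as.integer(chrom)) %% nrow(.NONPAL_PAIRS) + 1L
  pair <- .NONPAL_PAIRS[pair_idx, , drop = FALSE]
  data.frame(snp = sprintf("rs%d%08d", as.integer(chrom), as.integer(pos)),
             chr = as.character(chrom), pos = pos,
             ea = pair[, 1], oa = pair[, 2], stringsAsFactors = FALSE)
}

sumstats_from <- function(layout, beta, se, eaf, n) {
  z <- beta / se
  data.frame(layout,
             eaf = eaf, beta = beta, se = rep(se, nrow(layout)),
             pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
             n = n, stringsAsFactors = FALSE)
}

## Randomly swap effect/other alleles on a fraction of rows (flipping
## beta and eaf), to exercise downstream harmonization.
swap_some_alleles <- function(x, fraction) {
  flip <- stats::runif(nrow(x)) < fraction
  tmp <- x$ea[flip]; x$ea[flip] <- x$oa[flip]; x$oa[flip] <- tmp
  x$beta[flip] <- -x$beta[flip]
  x$eaf[flip] <- 1 - x$eaf[flip]
  x
}

#' Simulate an aligned eQTL/GWAS locus pair
#'
#' Generates summary statistics for one cis locus measured for two
#' traits (gene expression and a side-effect-proxy phenotype) under one
#' of the five causal configurations:
#' \itemize{
#'   \item `H0`: no causal variant for either trait;
#'   \item `H1`: expression has a causal variant, the phenotype none
#'     (the null scenario of the MR screen);
#'   \item `H2`: the phenotype has a causal variant, expression none;
#'   \item `H3`: both traits causal, at distinct variants;
#'   \item `H4`: both traits causal at the same variant, with phenotype
#'     effect `theta * beta_zx`.
#' }
#' LD is AR(1) by adjacency (`rho^|i-j|`); marginal effects are the LD
#' row times the causal-effect vector; estimate noise has the analytic
#' standard error `1/sqrt(2 maf (1-maf) n)`. A fraction of GWAS rows
#' have effect/other alleles swapped (with beta sign and eaf flipped) to
#' exercise harmonization. Deterministic given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param hypothesis One of `"H0", "H1", "H2", "H3", "H4"`.
#' @param m_snps Number of variants at the locus.
#' @param ld_rho AR(1) LD correlation in `[0, 1)`.
#' @param maf Minor-allele frequency in (0, 0.5).
#' @param beta_zx True causal eQTL effect.
#' @param theta True causal effect of expression on the phenotype.
#' @param n_eqtl,n_gwas Sample sizes.
#' @param seed Integer RNG seed.
#' @param gene,tissue,chrom,start_pos Locus labels and coordinates.
#' @param causal_index,causal_index2 Causal variant positions for
#'   expression and (under H2/H3) the phenotype; defaults are m/3 and
#'   2m/3. Under H3 they must differ.
#' @param swap_fraction Fraction of GWAS rows with swapped alleles.
#' @return List with `eqtl` (records carrying `gene` and `tissue`),
#'   `gwas`, `causal_index_exposure`, `causal_index_outcome` (NA when
#'   absent) and `hypothesis`.
#' @export
simulate_locus_pair <- function(hypothesis = c("H4", "H0", "H1", "H2", "H3"),
                                m_snps = 50, ld_rho = 0.9, maf = 0.3,
                                beta_zx = 0.3, theta = 0.5,
                                n_eqtl = 50000, n_gwas = 50000, seed = 1,
                                gene = "GENE1", tissue = "cortex",
                                chrom = 1, start_pos = 1e6,
                                causal_index = NULL, causal_index2 = NULL,
                                swap_fraction = 0.3) {
  hypothesis <- match.arg(hypothesis)
  if (!is.numeric(maf) || maf <= 0 || maf >= 0.5) {
    stop("maf must be in (0, 0.5)", call. = FALSE)
  }
  stopifnot(m_snps >= 1)
  if (is.null(causal_index)) causal_index <- max(1L, m_snps %/% 3L)
  if (is.null(causal_index2)) {
    causal_index2 <- max(1L, min(m_snps, (2L * m_snps) %/% 3L))
  }
  if (hypothesis == "H3" && causal_index == causal_index2) {
    stop("H3 requires distinct causal indices for the two traits",
         call. = FALSE)
  }
  with_seed(seed, {
    sigma_chol <- chol(ar1_sigma(m_snps, ld_rho))
    layout <- locus_layout(m_snps, chrom, start_pos)
    se1 <- 1 / sqrt(2 * maf * (1 - maf) * n_eqtl)
    se2 <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)

    c1 <- numeric(m_snps)
    c2 <- numeric(m_snps)
    idx1 <- NA_integer_; idx2 <- NA_integer_
    if (hypothesis %in% c("H1", "H3", "H4")) {
      c1[causal_index] <- beta_zx
      idx1 <- causal_index
    }
    if (hypothesis == "H4") { c2[causal_index] <- theta * beta_zx
                              idx2 <- causal_index }
    if (hypothesis == "H3") { c2[causal_index2] <- theta * beta_zx
                              idx2 <- causal_index2 }
    if (hypothesis == "H2") { c2[causal_index2] <- theta * beta_zx
                              idx2 <- causal_index2 }

    b1 <- sim_marginal_stats(sigma_chol, c1, se1)
    b2 <- sim_marginal_stats(sigma_chol, c2, se2)
    eqtl <- sumstats_from(layout, b1, se1, maf, n_eqtl)
    eqtl$gene <- gene
    eqtl$tissue <- tissue
    gwas <- swap_some_alleles(sumstats_from(layout, b2, se2, maf, n_gwas),
                              swap_fraction)
    list(eqtl = eqtl, gwas = gwas,
         causal_index_exposure = idx1, causal_index_outcome = idx2,
         hypothesis = hypothesis)
  })
}

#' Simulate a multi-laboratory binding-affinity table
#'
#' Emulates the structure of public Ki repositories: per measured
#' (drug, receptor) pair, 3-8 measurements log-normally scattered around
#' the true Ki (`noise_sd_log10` on the log10 scale), with occasional
#' order-of-magnitude outliers (multiplied by 10^2-10^3 at
#' `outlier_rate`, exercising the trimmed mean) and whole pairs left
#' unmeasured at `missing_rate` (a single blank-Ki row, exercising the
#' default-pKi imputation path).
#'
#' @param drugs,receptors Character vectors; the table covers their full
#'   cross product.
#' @param truth Optional `data.frame(drug, receptor, true_ki_nM,
#'   action)`; generated when `NULL` (true Ki log-uniform on
#'   10^[0.5, 3.5] nM).
#' @param noise_sd_log10 Measurement noise SD on the log10(nM) scale.
#' @param outlier_rate,missing_rate Rates in [0, 1].
#' @param n_measurements Integer vector the per-pair measurement count is
#'   drawn from.
#' @param seed Integer RNG seed.
#' @return List with `rows` (columns `drug, receptor, ki_nM, action,
#'   source`) and `truth` (with a `measured` flag added).
#' @export
simulate_affinity_table <- function(drugs, receptors, truth = NULL,
                                    noise_sd_log10 = 0.3,
                                    outlier_rate = 0.05,
                                    missing_rate = 0.15,
                                    n_measurements = 3:8, seed = 1) {
  stopifnot(outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    if (is.null(truth)) {
      truth <- expand.grid(drug = drugs, receptor = receptors,
                           stringsAsFactors = FALSE)
      truth$true_ki_nM <- 10^stats::runif(nrow(truth), 0.5, 3.5)
      truth$action <- sample(c("antagonist", "agonist", "inverse_agonist",
                               "positive_modulator"),
                             nrow(truth), replace = TRUE)
    }
    truth$measured <- stats::runif(nrow(truth)) >= missing_rate
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      if (!truth$measured[i]) {
        return(data.frame(drug = truth$drug[i], receptor = truth$receptor[i],
                          ki_nM = NA_real_, action = truth$action[i],
                          source = "synthetic", stringsAsFactors = FALSE))
      }
      k <- if (length(n_measurements) == 1) n_measurements
           else sample(n_measurements, 1)
      ki <- 10^(log10(truth$true_ki_nM[i]) +
                  stats::rnorm(k, 0, noise_sd_log10))
      out <- stats::runif(k) < outlier_rate
      ki[out] <- ki[out] * 10^stats::runif(sum(out), 2, 3)
      data.frame(drug = truth$drug[i], receptor = truth$receptor[i],
                 ki_nM = ki, action = truth$action[i],
                 source = sprintf("synthetic_lab%d", seq_len(k)),
                 stringsAsFactors = FALSE)
    })
    list(rows = do.call(rbind, rows), truth = truth)
  })
}

#' Default study design for the simulator
#'
#' Describes the synthetic study [simulate_study()] generates: 2 drugs
#' binding 6 receptor genes, 4 side-effects proxied by 5 GWAS phenotypes
#' (one side-effect has two proxies, exercising the one-result-per-pair
#' rule), 5 brain tissues plus blood, 50-SNP cis loci with AR(1) LD
#' rho = 0.9, MAF 0.3, eQTL effect 0.3 and causal expression-phenotype
#' effect theta = 0.5 at n = 50,000 for both traits. Planted (gene,
#' phenotype) pairs are H4 loci; decoys are H3 (distinct causal
#' variants) and H1 (outcome-null) loci.
#'
#' @return Named list of study parameters; edit fields to change the
#'   design.
#' @export
default_study_config <- function() {
  genes <- data.frame(
    gene = c("CHRM3", "HRH1", "GABRA1", "ADRA1A", "DRD2", "HTR2A"),
    chrom = c("1", "3", "5", "8", "11", "13"),
    start = 2e6, end = 2.05e6, stringsAsFactors = FALSE)
  se_map <- data.frame(
    side_effect = c("weight_gain", "weight_gain", "neutropenia",
                    "blood_pressure", "sedation"),
    phenotype_id = c("pheno_bmi", "pheno_weight", "pheno_neutrophil_count",
                     "pheno_systolic_bp", "pheno_sleep_duration"),
    brain_relevant = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  planted <- data.frame(
    gene = c("DRD2", "CHRM3", "HRH1", "GABRA1", "HTR2A", "ADRA1A"),
    phenotype_id = c("pheno_bmi", "pheno_weight", "pheno_systolic_bp",
                     "pheno_neutrophil_count", "pheno_sleep_duration",
                     "pheno_systolic_bp"),
    stringsAsFactors = FALSE)
  h3_decoys <- data.frame(
    gene = c("DRD2", "CHRM3", "GABRA1", "HTR2A", "HRH1", "ADRA1A"),
    phenotype_id = c("pheno_neutrophil_count", "pheno_systolic_bp",
                     "pheno_bmi", "pheno_weight", "pheno_sleep_duration",
                     "pheno_bmi"),
    stringsAsFactors = FALSE)
  list(
    drugs = c("clozapine", "olanzapine"),
    dose_equivalents = c(clozapine = 1, olanzapine = 0.75),
    genes = genes,
    side_effect_map = se_map,
    planted = planted,
    h3_decoys = h3_decoys,
    tissues = c("basal_ganglia", "cerebellum", "cortex", "hippocampus",
                "spinal_cord", "blood"),
    m_snps = 50, ld_rho = 0.9, maf = 0.3,
    beta_zx = 0.3, theta = 0.5,
    n_eqtl = 50000, n_gwas = 50000,
    noise_sd_log10 = 0.3, outlier_rate = 0.05, missing_rate = 0.15,
    swap_fraction = 0.3
  )
}

#' Simulate a complete study input bundle
#'
#' Writes all pipeline inputs to `out_dir` -- `eqtl.tsv` (all genes and
#' tissues), `gwas/<phenotype_id>.tsv`, `affinity.csv`,
#' `side_effect_map.csv`, `dose_equivalents.csv`, `genes.tsv` -- plus a
#' `truth.json` manifest labelling every locus with its causal scenario
#' and listing the planted (drug, receptor, side-effect) triples.
#' Planted loci are H4 with nonzero theta; H3 decoys place the two
#' causal variants a third of the locus apart; every remaining (gene,
#' phenotype) pair is an outcome-null H1 locus. The same eQTL statistics
#' serve every phenotype (one expression dataset per gene and tissue, as
#' in real data); each tissue gets independent estimate noise around the
#' shared causal signal. Deterministic given `seed`.
#'
#' @param study Study design list, see [default_study_config()].
#' @param seed Integer RNG seed.
#' @param out_dir Directory to create the bundle in.
#' @return List with `paths` (named as `default_config()$paths`, plus
#'   `truth`), and `truth` (the manifest as an R list).
#' @export
simulate_study <- function(study = default_study_config(), seed = 1,
                           out_dir) {
  stopifnot(!missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "gwas"), showWarnings = FALSE)

  genes <- study$genes
  se_map <- study$side_effect_map
  m <- study$m_snps
  idx1 <- max(1L, m %/% 3L)
  idx2 <- max(1L, min(m, (2L * m) %/% 3L))

  scen_key <- function(g, p) paste(g, p, sep = "\r")
  scenario_of <- rep("H1", nrow(genes) * length(unique(se_map$phenotype_id)))
  phenos <- unique(se_map$phenotype_id)
  names(scenario_of) <- as.vector(outer(genes$gene, phenos, scen_key))
  scenario_of[scen_key(study$planted$gene, study$planted$phenotype_id)] <- "H4"
  scenario_of[scen_key(study$h3_decoys$gene,
                       study$h3_decoys$phenotype_id)] <- "H3"

  res <- with_seed(seed, {
    sigma_chol <- chol(ar1_sigma(m, study$ld_rho))
    se_e <- 1 / sqrt(2 * study$maf * (1 - study$maf) * study$n_eqtl)
    se_g <- 1 / sqrt(2 * study$maf * (1 - study$maf) * study$n_gwas)

    eqtl_blocks <- list()
    layouts <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene[i]
      layouts[[g]] <- locus_layout(m, genes$chrom[i], genes$start[i])
      c1 <- numeric(m); c1[idx1] <- study$beta_zx
      for (tis in study$tissues) {
        b1 <- sim_marginal_stats(sigma_chol, c1, se_e)
        blk <- sumstats_from(layouts[[g]], b1, se_e, study$maf, study$n_eqtl)
        blk$gene <- g; blk$tissue <- tis
        eqtl_blocks[[length(eqtl_blocks) + 1L]] <- blk
      }
    }
    eqtl <- do.call(rbind, eqtl_blocks)

    gwas_tables <- list()
    scen_rows <- list()
    for (p in phenos) {
      blocks <- list()
      for (i in seq_len(nrow(genes))) {
        g <- genes$gene[i]
        hyp <- scenario_of[[scen_key(g, p)]]
        c2 <- numeric(m)
        io <- NA_integer_
        if (hyp == "H4") { c2[idx1] <- study$theta * study$beta_zx
                           io <- idx1 }
        if (hyp == "H3") { c2[idx2] <- study$theta * study$beta_zx
                           io <- idx2 }
        b2 <- sim_marginal_stats(sigma_chol, c2, se_g)
        blk <- swap_some_alleles(
          sumstats_from(layouts[[g]], b2, se_g, study$maf, study$n_gwas),
          study$swap_fraction)
        blocks[[g]] <- blk
        scen_rows[[length(scen_rows) + 1L]] <- data.frame(
          gene = g, phenotype_id = p, hypothesis = hyp,
          causal_index_exposure = idx1, causal_index_outcome = io,
          theta = if (hyp %in% c("H3", "H4")) study$theta else 0,
          stringsAsFactors = FALSE)
      }
      gwas_tables[[p]] <- do.call(rbind, blocks)
    }

    aff <- simulate_affinity_table(
      study$drugs, genes$gene,
      noise_sd_log10 = study$noise_sd_log10,
      outlier_rate = study$outlier_rate,
      missing_rate = study$missing_rate,
      seed = sample.int(2^30, 1))
    list(eqtl = eqtl, gwas_tables = gwas_tables,
         scenarios = do.call(rbind, scen_rows), aff = aff)
  })

  paths <- list(
    eqtl = file.path(out_dir, "eqtl.tsv"),
    gwas_dir = file.path(out_dir, "gwas"),
    affinity = file.path(out_dir, "affinity.csv"),
    side_effect_map = file.path(out_dir, "side_effect_map.csv"),
    dose_equivalents = file.path(out_dir, "dose_equivalents.csv"),
    genes = file.path(out_dir, "genes.tsv")
  )
  write_tsv(res$eqtl, paths$eqtl)
  for (p in names(res$gwas_tables)) {
    write_tsv(res$gwas_tables[[p]], file.path(out_dir, "gwas",
                                              paste0(p, ".tsv")))
  }
  aff_rows <- res$aff$rows
  aff_rows$ki_nM <- ifelse(is.na(aff_rows$ki_nM), "",
                           sprintf("%.15g", aff_rows$ki_nM))
  utils::write.csv(aff_rows, paths$affinity, row.names = FALSE, quote = FALSE)
  utils::write.csv(se_map, paths$side_effect_map, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(drug = names(study$dose_equivalents),
                              dose_equivalent =
                                unname(study$dose_equivalents)),
                   paths$dose_equivalents, row.names = FALSE, quote = FALSE)
  write_tsv(genes, paths$genes)

  planted_se <- merge(study$planted, se_map, by = "phenotype_id")
  planted_triples <- unique(do.call(rbind, lapply(study$drugs, function(d) {
    data.frame(drug = d, receptor = planted_se$gene,
               side_effect = planted_se$side_effect,
               stringsAsFactors = FALSE)
  })))
  planted_triples <-
    planted_triples[order(planted_triples$drug, planted_triples$receptor,
                          planted_triples$side_effect), , drop = FALSE]
  rownames(planted_triples) <- NULL

  truth <- list(
    seed = as.integer(seed),
    parameters = study[c("m_snps", "ld_rho", "maf", "beta_zx", "theta",
                         "n_eqtl", "n_gwas", "noise_sd_log10",
                         "outlier_rate", "missing_rate")],
    scenarios = res$scenarios,
    planted_triples = planted_triples,
    affinity_truth = res$aff$truth
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  paths$truth <- truth_path
  list(paths = paths, truth = truth)
}
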