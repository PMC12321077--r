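## Approximate-Bayes-factor colocalization: decide per (gene, phenotype)
## locus whether the eQTL and GWAS signals share a single causal variant.

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's approximate Bayes factor for association at a single
#' variant, on the log scale: with `z = beta/se`, `V = se^2` and
#' `W = prior_sd^2`,
#' `log ABF = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W)`.
#' Larger values favour association; in the vanishing-prior limit
#' (`W -> 0`) the value tends to 0 for any z.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param prior_sd Prior standard deviation of the true effect, > 0.
#' @return Log ABF value(s).
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  z2 <- (beta / se)^2
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + 0.5 * z2 * r
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Colocalization of two traits at one locus
#'
#' Single-causal-variant colocalization from summary statistics. For an
#' aligned locus of m variants measured for two traits, computes per-SNP
#' log ABFs and the posterior probabilities of the five causal
#' configurations: H0 no association with either trait, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4
#' one shared causal variant. Unnormalized weights (with per-SNP ABFs
#' `A1_i`, `A2_i` and priors `p1`, `p2`, `p12`):
#' `H0 = 1`, `H1 = p1 sum_i A1_i`, `H2 = p2 sum_i A2_i`,
#' `H3 = p1 p2 (sum_i A1_i sum_j A2_j - sum_i A1_i A2_i)`,
#' `H4 = p12 sum_i A1_i A2_i`.
#' All sums are evaluated in log space with log-sum-exp, so loci with
#' |z| up to 60 and beyond remain finite. A single-SNP locus has H3
#' weight exactly 0 (no distinct-variant configuration exists).
#'
#' @param locus `data.frame` with columns `snp_id, beta1, se1, beta2,
#'   se2`, alleles already harmonized between the traits.
#' @param priors List with per-SNP prior probabilities `p1`, `p2`
#'   (trait-specific causality) and `p12` (shared causality).
#' @param prior_sd1,prior_sd2 Effect-size prior SDs for the two traits
#'   (0.15 for quantitative traits, 0.2 for binary traits on the
#'   log-odds scale).
#' @return List of class `coloc_result`: `pp` (named H0..H4, summing to
#'   1), `n_snps`, and `lbf1`, `lbf2` (per-SNP log ABFs).
#' @export
coloc_abf <- function(locus, priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  stopifnot(nrow(locus) >= 1, all(locus$se1 > 0), all(locus$se2 > 0))
  l1 <- log_abf(locus$beta1, locus$se1, prior_sd1)
  l2 <- log_abf(locus$beta2, locus$se2, prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)

  lw <- c(
    H0 = 0,
    H1 = log(priors$p1) + s1,
    H2 = log(priors$p2) + s2,
    H3 = -Inf,
    H4 = log(priors$p12) + s12
  )
  if (nrow(locus) > 1) {
    ## sum over i != j equals S1*S2 - S12; the difference is computed in
    ## log space and clamped at 0 when one SNP carries all the mass.
    d <- s12 - (s1 + s2)
    if (d < 0) {
      lw[["H3"]] <- log(priors$p1) + log(priors$p2) + s1 + s2 +
        log1p(-exp(d))
    }
  }
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_snps = nrow(locus), lbf1 = l1, lbf2 = l2),
            class = "coloc_result")
}

#' Apply the colocalization gate
#'
#' A locus passes when there is evidence of a shared causal variant,
#' `PP.H4 >= h4_min` (default 0.6, inclusive), while also lacking
#' evidence of distinct causal variants, `PP.H3 < h3_max` (default 0.1).
#' The relaxed H4 threshold (vs the conventional 0.8) admits
#' shared-signal loci where the outcome trait is under-powered, and the
#' H3 condition separates them from loci with genuinely different causal
#' variants.
#'
#' @param result A `coloc_result` from [coloc_abf()], or a 5-vector of
#'   posterior probabilities ordered H0..H4.
#' @param h4_min,h3_max Gate thresholds.
#' @return Logical.
#' @export
passes_coloc <- function(result, h4_min = 0.6, h3_max = 0.1) {
  pp <- if (inherits(result, "coloc_result")) result$pp else result
  stopifnot(length(pp) == 5)
  unname(pp[5] >= h4_min && pp[4] < h3_max)
}

#' Route a phenotype to its eQTL dataset
#'
#' Colocalization (and the beta entering the score) uses the brain eQTL
#' dataset when the side-effect is relevant to brain function, and the
#' blood dataset otherwise. The `brain_relevant` flag is data carried by
#' the side-effect map, not an inference.
#'
#' @param phenotype_id Phenotype label.
#' @param se_map Side-effect map from [read_side_effect_map()].
#' @return `"brain"` or `"blood"`.
#' @export
route_dataset <- function(phenotype_id, se_map) {
  hits <- se_map$brain_relevant[se_map$phenotype_id == phenotype_id]
  if (length(hits) == 0) {
    stop("unmapped phenotype: ", phenotype_id, call. = FALSE)
  }
  if (length(unique(hits)) > 1) {
    stop("conflicting brain_relevant flags for phenotype: ", phenotype_id,
         call. = FALSE)
  }
  if (hits[1]) "brain" else "blood"
}

#' Build an aligned locus pair for colocalization
#'
#' Joins the eQTL records of one (gene, tissue) locus with a phenotype's
#' GWAS records by SNP id, harmonizes alleles (sign-correcting swapped
#' outcome records, dropping palindromic and allele-mismatched variants),
#' and returns the aligned table `coloc_abf()` consumes.
#'
#' @param eqtl_locus eQTL records of one gene and tissue (cis window).
#' @param gwas GWAS records for the phenotype.
#' @return `data.frame(snp_id, beta1, se1, beta2, se2)`; zero rows when
#'   no variant survives.
#' @export
build_locus_pair <- function(eqtl_locus, gwas) {
  merged <- merge(eqtl_locus, gwas, by = "snp",
                  suffixes = c("_x", "_y"), sort = FALSE)
  if (nrow(merged) == 0) {
    return(data.frame(snp_id = character(0), beta1 = numeric(0),
                      se1 = numeric(0), beta2 = numeric(0),
                      se2 = numeric(0)))
  }
  status <- harmonize_status(merged$ea_x, merged$oa_x,
                             merged$ea_y, merged$oa_y)
  keep <- status %in% c("same", "flip")
  merged <- merged[keep, , drop = FALSE]
  sgn <- ifelse(status[keep] == "flip", -1, 1)
  out <- data.frame(snp_id = merged$snp,
                    beta1 = merged$beta_x, se1 = merged$se_x,
                    beta2 = sgn * merged$beta_y, se2 = merged$se_y,
                    stringsAsFactors = FALSE)
  out[order(out$snp_id), , drop = FALSE]
}
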