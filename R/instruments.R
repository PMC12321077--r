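## Instrument selection, the phenome-wide screen, Wald-ratio MR, and the
## F-statistic / FDR gates.

#' First-stage F-statistic from summary statistics
#'
#' Computed as the squared t ratio `(beta_zx / se_zx)^2`. Instruments
#' with `F <= f_min` (default 22) are treated as weak and excluded from
#' MR by the screen.
#'
#' @param beta_zx SNP-exposure effect estimate(s).
#' @param se_zx Standard error(s), > 0.
#' @return Numeric F value(s), >= 0.
#' @export
f_statistic <- function(beta_zx, se_zx) {
  stopifnot(all(se_zx > 0))
  (beta_zx / se_zx)^2
}

#' Select cis-eQTL instruments for receptor genes
#'
#' For each gene and each tissue, retains the single smallest-p variant
#' lying within the cis window (default +/-1 Mb of the gene interval,
#' same chromosome). Trans variants are excluded. The same variant may
#' lead several tissues; it then yields one instrument per (gene, tissue)
#' with a shared SNP. Ties on p-value are broken by the lexicographically
#' smallest SNP id for determinism. Genes with no cis association are
#' dropped with a logged message.
#'
#' @param eqtl eQTL summary-statistics table from
#'   `read_sumstats(..., eqtl = TRUE)`.
#' @param genes Gene annotation `data.frame(gene, chrom, start, end)`.
#' @param cis_window_bp Window in bp added on each side of the gene
#'   interval.
#' @return `data.frame` of instruments: one row per (gene, tissue) with
#'   the lead SNP's summary statistics and its `f_stat`.
#' @export
select_instruments <- function(eqtl, genes, cis_window_bp = 1e6) {
  stopifnot(all(c("gene", "tissue") %in% names(eqtl)))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    sub <- eqtl[eqtl$gene == g &
                  as.character(eqtl$chr) == as.character(genes$chrom[i]) &
                  eqtl$pos >= genes$start[i] - cis_window_bp &
                  eqtl$pos <= genes$end[i] + cis_window_bp, , drop = FALSE]
    if (nrow(sub) == 0) {
      message("select_instruments: no cis association for gene ", g)
      next
    }
    for (tis in sort(unique(sub$tissue))) {
      st <- sub[sub$tissue == tis, , drop = FALSE]
      st <- st[order(st$pval, st$snp), , drop = FALSE]
      rows[[length(rows) + 1L]] <- st[1, , drop = FALSE]
    }
  }
  if (!length(rows)) {
    out <- eqtl[0, , drop = FALSE]
    out$f_stat <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$f_stat <- f_statistic(out$beta, out$se)
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wald-ratio MR estimate
#'
#' Single-instrument Mendelian randomization estimate
#' `beta_iv = beta_zy / beta_zx` with, by default, the first-order
#' delta-method standard error `se_iv = |se_zy / beta_zx|` (the exposure
#' uncertainty is ignored, the standard first-term approximation; the
#' second-order form adding `beta_zy^2 se_zx^2 / beta_zx^4` is available
#' via `method = "second_order"`). The p-value is the two-sided normal
#' test of `beta_iv / se_iv`.
#'
#' @param beta_zy,se_zy SNP-outcome effect and SE.
#' @param beta_zx,se_zx SNP-exposure effect and SE.
#' @param method `"first_order"` (default) or `"second_order"` SE.
#' @return `data.frame(beta_iv, se_iv, pval)`, vectorized over inputs.
#' @export
wald_ratio <- function(beta_zy, se_zy, beta_zx, se_zx,
                       method = c("first_order", "second_order")) {
  method <- match.arg(method)
  if (any(beta_zx == 0)) stop("undefined ratio: beta_zx == 0", call. = FALSE)
  stopifnot(all(se_zy > 0), all(se_zx > 0))
  beta_iv <- beta_zy / beta_zx
  se_iv <- if (method == "first_order") {
    abs(se_zy / beta_zx)
  } else {
    sqrt(se_zy^2 / beta_zx^2 + beta_zy^2 * se_zx^2 / beta_zx^4)
  }
  pval <- 2 * stats::pnorm(-abs(beta_iv / se_iv))
  data.frame(beta_iv = beta_iv, se_iv = se_iv, pval = pval)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, applied once across
#' the entire screen per run. Delegates to [stats::p.adjust()].
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted q-values, `qval >= pval` element-wise.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

## Internal: resolve a GWAS store (named list of data.frames, or a
## directory of <phenotype_id>.tsv files) to one phenotype's table.
gwas_lookup <- function(gwas_store, phenotype_id) {
  if (is.list(gwas_store) && !is.null(gwas_store[[phenotype_id]])) {
    return(gwas_store[[phenotype_id]])
  }
  if (is.character(gwas_store) && length(gwas_store) == 1L) {
    path <- file.path(gwas_store, paste0(phenotype_id, ".tsv"))
    if (file.exists(path)) return(read_sumstats(path))
  }
  NULL
}

#' Phenome-wide side-effect screen
#'
#' Runs every F-passing instrument against every mapped phenotype:
#' extracts the instrument SNP's association from the phenotype's GWAS
#' summary statistics, harmonizes alleles (sign-correcting swapped
#' records, rejecting palindromic ones), and computes the Wald ratio.
#' Benjamini-Hochberg adjustment is applied jointly across the full
#' screen, and results with `qval >= fdr` are dropped. Pairs whose
#' outcome record is absent or not harmonizable are skipped with a log
#' entry; the attributes account exactly for every (instrument, map-row)
#' combination: `n_combinations == n_tested + n_skipped`.
#'
#' @param instruments Instrument table from [select_instruments()].
#' @param gwas_store Named list of GWAS tables keyed by phenotype id, or
#'   a directory containing `<phenotype_id>.tsv` files.
#' @param se_map Side-effect map from [read_side_effect_map()].
#' @param config Run configuration ([default_config()]): uses `f_min`,
#'   `fdr`, `wald_se_method`.
#' @return `data.frame` of FDR-passing results (gene, tissue, snp,
#'   side_effect, phenotype_id, beta_zy, se_zy, beta_zx, se_zx, f_stat,
#'   beta_iv, se_iv, pval, qval), with attributes `n_combinations`,
#'   `n_tested`, `n_skipped`, `skipped` (a data.frame of reasons) and
#'   `all_results` (the unfiltered tested set with q-values).
#' @export
screen <- function(instruments, gwas_store, se_map,
                   config = default_config()) {
  inst <- instruments[instruments$f_stat > config$f_min, , drop = FALSE]
  n_weak <- nrow(instruments) - nrow(inst)
  if (n_weak > 0) {
    message("screen: excluded ", n_weak, " weak instrument(s) with F <= ",
            config$f_min)
  }
  res <- list(); skipped <- list()
  phenos <- unique(se_map$phenotype_id)
  tables <- lapply(phenos, function(p) gwas_lookup(gwas_store, p))
  names(tables) <- phenos

  for (m in seq_len(nrow(se_map))) {
    pid <- se_map$phenotype_id[m]
    sef <- se_map$side_effect[m]
    gtab <- tables[[pid]]
    for (i in seq_len(nrow(inst))) {
      row <- inst[i, ]
      skip <- function(reason) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          gene = row$gene, tissue = row$tissue, snp = row$snp,
          side_effect = sef, phenotype_id = pid, reason = reason,
          stringsAsFactors = FALSE)
      }
      if (is.null(gtab)) { skip("phenotype_unresolved"); next }
      hit <- gtab[gtab$snp == row$snp, , drop = FALSE]
      if (nrow(hit) == 0) { skip("snp_absent"); next }
      h <- harmonize(row[, c("snp", "ea", "oa", "beta", "eaf")],
                     hit[1, c("snp", "ea", "oa", "beta", "eaf")])
      if (!h$ok) { skip(h$reason); next }
      wr <- wald_ratio(h$outcome$beta, hit$se[1], row$beta, row$se,
                       method = config$wald_se_method)
      res[[length(res) + 1L]] <- data.frame(
        gene = row$gene, tissue = row$tissue, snp = row$snp,
        side_effect = sef, phenotype_id = pid,
        beta_zy = h$outcome$beta, se_zy = hit$se[1],
        beta_zx = row$beta, se_zx = row$se, f_stat = row$f_stat,
        beta_iv = wr$beta_iv, se_iv = wr$se_iv, pval = wr$pval,
        stringsAsFactors = FALSE)
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(0), tissue = character(0),
               snp = character(0), side_effect = character(0),
               phenotype_id = character(0), reason = character(0))
  if (nrow(skipped) > 0) {
    message("screen: skipped ", nrow(skipped), " combination(s)")
  }
  all_res <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(0), tissue = character(0),
               snp = character(0), side_effect = character(0),
               phenotype_id = character(0), beta_zy = numeric(0),
               se_zy = numeric(0), beta_zx = numeric(0),
               se_zx = numeric(0), f_stat = numeric(0),
               beta_iv = numeric(0), se_iv = numeric(0), pval = numeric(0))
  all_res$qval <- if (nrow(all_res)) bh_fdr(all_res$pval) else numeric(0)
  out <- all_res[all_res$qval < config$fdr, , drop = FALSE]
  out <- out[order(out$side_effect, out$gene, out$tissue, out$phenotype_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_combinations") <- nrow(inst) * nrow(se_map)
  attr(out, "n_tested") <- nrow(all_res)
  attr(out, "n_skipped") <- nrow(skipped)
  attr(out, "skipped") <- skipped
  attr(out, "all_results") <- all_res
  out
}

#' Retain one result per side-effect/receptor pair
#'
#' The screen can hit one side-effect through several proxy phenotypes
#' and several tissues; exactly one result is kept per (side_effect,
#' gene) pair. Selection: smallest q-value, ties broken by larger
#' F-statistic, then by lexicographically smallest SNP id, so the result
#' is deterministic.
#'
#' @param results MR results `data.frame` with `side_effect, gene, qval,
#'   f_stat, snp` columns.
#' @return Deduplicated `data.frame`, one row per pair.
#' @export
dedupe_pair_results <- function(results) {
  if (nrow(results) == 0) return(results)
  key <- paste(results$side_effect, results$gene, sep = "\r")
  picked <- vapply(split(seq_len(nrow(results)), key), function(idx) {
    sub <- results[idx, ]
    idx[order(sub$qval, -sub$f_stat, sub$snp)][1]
  }, integer(1))
  out <- results[sort(unname(picked)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
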