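## Stage orchestration. Each stage reads the raw inputs named in the
## config plus prior-stage TSVs from the output directory, and writes its
## own TSV there, so stages can be rerun in isolation (as the CLI
## subcommands do). run_pipeline() chains them and writes a JSON run
## manifest.

stage_path <- function(config, name) file.path(config$out_dir, name)

#' Affinity stage
#'
#' Reads the raw binding-affinity CSV, summarizes every (drug, receptor)
#' pair (discard threshold, trimmed mean, pKi scaling, default
#' imputation) and writes `affinity_summary.tsv`.
#'
#' @param config Validated run configuration with `paths` and `out_dir`
#'   set.
#' @return The affinity summary `data.frame`, invisibly.
#' @export
stage_affinity <- function(config) {
  aff <- read_affinity_table(config$paths$affinity)
  summ <- summarize_affinity_table(aff, config)
  write_tsv(summ, stage_path(config, "affinity_summary.tsv"))
  invisible(summ)
}

#' Instrument-selection stage
#'
#' Reads the eQTL table and gene annotation, selects the lead cis SNP
#' per (gene, tissue) with its F-statistic, and writes
#' `instruments.tsv`.
#'
#' @inheritParams stage_affinity
#' @return The instrument `data.frame`, invisibly.
#' @export
stage_instruments <- function(config) {
  eqtl <- read_sumstats(config$paths$eqtl, eqtl = TRUE)
  genes <- read_gene_table(config$paths$genes)
  inst <- select_instruments(eqtl, genes, config$cis_window_bp)
  write_tsv(inst, stage_path(config, "instruments.tsv"))
  invisible(inst)
}

#' Screening stage
#'
#' Reads `instruments.tsv`, runs the phenome-wide Wald-ratio screen
#' against the GWAS store with joint Benjamini-Hochberg adjustment, and
#' writes the FDR-passing results to `screen.tsv` (the unfiltered tested
#' set goes to `screen_all.tsv`).
#'
#' @inheritParams stage_affinity
#' @return The filtered screen `data.frame` (with accounting
#'   attributes), invisibly.
#' @export
stage_screen <- function(config) {
  inst <- read_tsv(stage_path(config, "instruments.tsv"))
  se_map <- read_side_effect_map(config$paths$side_effect_map)
  scr <- screen(inst, config$paths$gwas_dir, se_map, config)
  write_tsv(scr, stage_path(config, "screen.tsv"))
  write_tsv(attr(scr, "all_results"), stage_path(config, "screen_all.tsv"))
  invisible(scr)
}

#' Colocalization stage
#'
#' For every screen-passing (gene, tissue, phenotype) whose tissue
#' belongs to the phenotype's routed eQTL dataset (brain tissues for
#' brain-relevant side-effects, blood otherwise), aligns the full cis
#' locus across the two traits and computes ABF colocalization
#' posteriors; writes `coloc.tsv`. Then applies the H4/H3 gate, resolves
#' multiple passing tissues per (gene, phenotype) to the one with the
#' highest PP.H4 (ties: smallest MR q-value), deduplicates to one result
#' per (side_effect, gene) pair, and writes the gated MR results to
#' `mr_gated.tsv`.
#'
#' @inheritParams stage_affinity
#' @return List with `coloc` and `gated` data.frames, invisibly.
#' @export
stage_coloc <- function(config) {
  scr <- read_tsv(stage_path(config, "screen.tsv"))
  se_map <- read_side_effect_map(config$paths$side_effect_map)
  eqtl <- read_sumstats(config$paths$eqtl, eqtl = TRUE)
  genes <- read_gene_table(config$paths$genes)

  empty_coloc <- data.frame(
    gene = character(0), tissue = character(0), phenotype_id = character(0),
    eqtl_source = character(0), n_snps = integer(0),
    pp0 = numeric(0), pp1 = numeric(0), pp2 = numeric(0),
    pp3 = numeric(0), pp4 = numeric(0), passed = logical(0))
  if (nrow(scr) == 0) {
    write_tsv(empty_coloc, stage_path(config, "coloc.tsv"))
    gated <- scr
    write_tsv(gated, stage_path(config, "mr_gated.tsv"))
    return(invisible(list(coloc = empty_coloc, gated = gated)))
  }

  routed_tissues <- function(pid) {
    if (route_dataset(pid, se_map) == "brain") config$brain_tissues
    else config$blood_tissues
  }
  binary <- if (is.null(config$binary_phenotypes)) character(0)
            else config$binary_phenotypes

  cand <- unique(scr[, c("gene", "tissue", "phenotype_id")])
  rows <- list()
  gwas_cache <- list()
  for (i in seq_len(nrow(cand))) {
    g <- cand$gene[i]; tis <- cand$tissue[i]; pid <- cand$phenotype_id[i]
    if (!tis %in% routed_tissues(pid)) next
    gi <- genes[genes$gene == g, ]
    if (nrow(gi) == 0) next
    if (is.null(gwas_cache[[pid]])) {
      gwas_cache[[pid]] <- gwas_lookup(config$paths$gwas_dir, pid)
    }
    locus_eqtl <- eqtl[eqtl$gene == g & eqtl$tissue == tis &
                         eqtl$pos >= gi$start - config$cis_window_bp &
                         eqtl$pos <= gi$end + config$cis_window_bp, ,
                       drop = FALSE]
    locus <- build_locus_pair(locus_eqtl, gwas_cache[[pid]])
    if (nrow(locus) == 0) next
    sd2 <- if (pid %in% binary) config$prior_sd_binary
           else config$prior_sd_quant
    cr <- coloc_abf(locus, config$coloc_priors,
                    prior_sd1 = config$prior_sd_quant, prior_sd2 = sd2)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, tissue = tis, phenotype_id = pid,
      eqtl_source = route_dataset(pid, se_map),
      n_snps = cr$n_snps,
      pp0 = cr$pp[["H0"]], pp1 = cr$pp[["H1"]], pp2 = cr$pp[["H2"]],
      pp3 = cr$pp[["H3"]], pp4 = cr$pp[["H4"]],
      passed = passes_coloc(cr, config$h4_min, config$h3_max),
      stringsAsFactors = FALSE)
  }
  coloc_tab <- if (length(rows)) do.call(rbind, rows) else empty_coloc
  coloc_tab <- coloc_tab[order(coloc_tab$gene, coloc_tab$tissue,
                               coloc_tab$phenotype_id), , drop = FALSE]
  rownames(coloc_tab) <- NULL
  write_tsv(coloc_tab, stage_path(config, "coloc.tsv"))

  gated <- merge(scr, coloc_tab[coloc_tab$passed,
                                c("gene", "tissue", "phenotype_id",
                                  "eqtl_source", "pp4")],
                 by = c("gene", "tissue", "phenotype_id"))
  if (nrow(gated) > 0) {
    ## one tissue per (gene, phenotype): highest PP.H4, ties by MR q-value
    key <- paste(gated$gene, gated$phenotype_id, sep = "\r")
    picked <- vapply(split(seq_len(nrow(gated)), key), function(idx) {
      sub <- gated[idx, ]
      idx[order(-sub$pp4, sub$qval, sub$tissue)][1]
    }, integer(1))
    gated <- gated[sort(unname(picked)), , drop = FALSE]
    gated <- dedupe_pair_results(gated)
  }
  gated <- gated[order(gated$side_effect, gated$gene), , drop = FALSE]
  rownames(gated) <- NULL
  write_tsv(gated, stage_path(config, "mr_gated.tsv"))
  invisible(list(coloc = coloc_tab, gated = gated))
}

#' Scoring stage
#'
#' Joins the gated MR results with affinity summaries and dose
#' equivalents into signed score terms (one per drug, side-effect and
#' receptor; non-binding pairs omitted with a log entry), computes
#' per-entry and per-drug scores with parametric-bootstrap standard
#' errors, and writes `scores.tsv` (the full per-term breakdown),
#' `score_entries.tsv`, `drug_scores.tsv`, `receptor_summary.tsv`,
#' `side_effect_summary.tsv` and `classification.tsv`.
#'
#' @inheritParams stage_affinity
#' @return List of the score tables, invisibly.
#' @export
stage_score <- function(config) {
  gated <- read_tsv(stage_path(config, "mr_gated.tsv"))
  affs <- read_tsv(stage_path(config, "affinity_summary.tsv"))
  dose <- read_dose_equivalents(config$paths$dose_equivalents)

  terms <- list()
  n_nonbinding <- 0L
  if (nrow(gated) > 0) for (i in seq_len(nrow(gated))) {
    mr <- gated[i, ]
    hits <- affs[affs$receptor == mr$gene, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      a <- hits[j, ]
      if (isTRUE(a$non_binding)) { n_nonbinding <- n_nonbinding + 1L; next }
      de <- dose$dose_equivalent[dose$drug == a$drug]
      if (length(de) == 0) {
        stop("no dose equivalent for drug: ", a$drug, call. = FALSE)
      }
      terms[[length(terms) + 1L]] <- data.frame(
        drug = a$drug, side_effect = mr$side_effect, receptor = mr$gene,
        snp = mr$snp, tissue = mr$tissue, phenotype_id = mr$phenotype_id,
        eqtl_source = mr$eqtl_source,
        beta_iv = mr$beta_iv, se_iv = mr$se_iv, qval = mr$qval,
        pp4 = mr$pp4, pki = a$pki,
        ki_mean_M = a$ki_mean_M, ki_se_M = a$ki_se_M,
        is_default = a$is_default, de = de, action = a$action,
        stringsAsFactors = FALSE)
    }
  }
  if (n_nonbinding > 0) {
    message("stage_score: omitted ", n_nonbinding,
            " non-binding drug-receptor term(s)")
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(drug = character(0), side_effect = character(0),
               receptor = character(0), snp = character(0),
               tissue = character(0), phenotype_id = character(0),
               eqtl_source = character(0), beta_iv = numeric(0),
               se_iv = numeric(0), qval = numeric(0), pp4 = numeric(0),
               pki = numeric(0), ki_mean_M = numeric(0),
               ki_se_M = numeric(0), is_default = logical(0),
               de = numeric(0), action = character(0))

  if (nrow(terms) > 0) {
    terms$direction <- direction_for_action(terms$action)
    terms$a_d <- dose_adjustment(terms$pki, terms$de)
    terms$signed_value <- terms$direction * terms$beta_iv *
      (terms$pki + terms$a_d)
    terms <- terms[order(terms$drug, terms$side_effect, terms$receptor), ,
                   drop = FALSE]
    rownames(terms) <- NULL
    boot <- bootstrap_scores(terms, n_boot = config$n_boot,
                             seed = config$seed, config = config)
  } else {
    terms$direction <- numeric(0)
    terms$a_d <- numeric(0)
    terms$signed_value <- numeric(0)
    boot <- list(entry = data.frame(drug = character(0),
                                    side_effect = character(0),
                                    se_signed = numeric(0),
                                    se_abs = numeric(0)),
                 drug = data.frame(drug = character(0),
                                   se_signed = numeric(0),
                                   se_abs = numeric(0)),
                 n_boot = config$n_boot)
  }

  agg <- aggregate_scores(terms, config)
  entries <- merge(agg$side_effect_summary, boot$entry,
                   by = c("drug", "side_effect"), all.x = TRUE)
  nt <- tapply(rep(1L, nrow(terms)),
               paste(terms$drug, terms$side_effect, sep = "\r"), sum)
  entries$n_terms <- if (nrow(entries))
    as.integer(nt[paste(entries$drug, entries$side_effect, sep = "\r")])
    else integer(0)
  entries <- entries[order(entries$drug, entries$side_effect), , drop = FALSE]
  rownames(entries) <- NULL
  drug_scores <- merge(agg$drug_scores, boot$drug, by = "drug", all.x = TRUE)
  drug_scores <- drug_scores[order(drug_scores$drug), , drop = FALSE]
  rownames(drug_scores) <- NULL

  write_tsv(terms, stage_path(config, "scores.tsv"))
  write_tsv(entries, stage_path(config, "score_entries.tsv"))
  write_tsv(drug_scores, stage_path(config, "drug_scores.tsv"))
  write_tsv(agg$receptor_summary, stage_path(config, "receptor_summary.tsv"))
  write_tsv(agg$side_effect_summary,
            stage_path(config, "side_effect_summary.tsv"))
  write_tsv(agg$classification, stage_path(config, "classification.tsv"))
  invisible(list(terms = terms, entries = entries,
                 drug_scores = drug_scores, aggregates = agg,
                 bootstrap = boot))
}

#' Reporting stage
#'
#' Re-derives the aggregate tables (per-drug, per-receptor,
#' per-side-effect, classification) from `scores.tsv` alone, so reports
#' can be regenerated without rerunning the analysis. Empty score tables
#' yield empty but schema-valid outputs.
#'
#' @inheritParams stage_affinity
#' @return The aggregate tables, invisibly.
#' @export
stage_report <- function(config) {
  terms <- read_tsv(stage_path(config, "scores.tsv"))
  agg <- aggregate_scores(terms, config)
  write_tsv(agg$drug_scores, stage_path(config, "drug_scores.tsv"))
  write_tsv(agg$receptor_summary, stage_path(config, "receptor_summary.tsv"))
  write_tsv(agg$side_effect_summary,
            stage_path(config, "side_effect_summary.tsv"))
  write_tsv(agg$classification, stage_path(config, "classification.tsv"))
  invisible(agg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes affinity summarization, instrument selection, the
#' phenome-wide screen with FDR control, the colocalization gate, and
#' scoring with bootstrap SEs, writing every stage TSV plus a
#' `manifest.json` (config hash, seed, per-stage row counts, package
#' version) to `config$out_dir`. Identical config, seed and inputs
#' produce byte-identical outputs.
#'
#' @param config Run configuration; validated before any computation.
#' @return Invisibly, a list with the score tables and the manifest.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  for (p in c("eqtl", "gwas_dir", "affinity", "side_effect_map",
              "dose_equivalents", "genes")) {
    if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
      stop("input not readable: ", p, call. = FALSE)
    }
  }
  if (is.null(config$out_dir)) stop("out_dir not set", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(name, fn) {
    tryCatch(fn(config),
             error = function(e) {
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  aff <- run_stage("affinity", stage_affinity)
  inst <- run_stage("instruments", stage_instruments)
  scr <- run_stage("screen", stage_screen)
  col <- run_stage("coloc", stage_coloc)
  sco <- run_stage("score", stage_score)

  manifest <- list(
    package = "sidefxmr",
    version = as.character(utils::packageVersion("sidefxmr")),
    seed = as.integer(config$seed),
    config_hash = config_hash(config),
    thresholds = config[c("fdr", "f_min", "h4_min", "h3_max",
                          "ki_discard_nM", "trim", "default_pki",
                          "default_pki_se", "n_boot", "cis_window_bp",
                          "nM_to_M")],
    row_counts = list(
      affinity_pairs = nrow(aff),
      instruments = nrow(inst),
      screen_combinations = attr(scr, "n_combinations"),
      screen_tested = attr(scr, "n_tested"),
      screen_skipped = attr(scr, "n_skipped"),
      screen_passed = nrow(scr),
      coloc_candidates = nrow(col$coloc),
      coloc_passed = sum(col$coloc$passed),
      mr_gated = nrow(col$gated),
      score_terms = nrow(sco$terms),
      score_entries = nrow(sco$entries)
    )
  )
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(sco, list(manifest = manifest)))
}
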