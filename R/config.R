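#' Default run configuration
#'
#' Returns the full set of tunable constants used by the pipeline, at their
#' standard values: the 10,000 nM discard threshold for binding-affinity
#' measurements, the 0.1 trimmed-mean proportion, the default imputed pKi of
#' 0.824 (SE 0.15) for drug-receptor pairs with no measurement, the
#' F-statistic cut-off of 22 against weak instruments, the screening FDR of
#' 0.05, the colocalization gate (PP.H4 >= 0.6 and PP.H3 < 0.1) with
#' single-variant priors p1 = p2 = 1e-4, p12 = 1e-5, the +/-1 Mb cis window,
#' and 1000 parametric-bootstrap iterations.
#'
#' `nM_to_M` is the factor applied to nanomolar Ki before the logarithmic
#' pKi scaling. The default 1e-8 places pKi on a 0-4.5 scale with the
#' 10,000 nM discard boundary at exactly pKi = 0; set it to 1e-9 for the
#' physical nanomolar-to-molar convention (which shifts the scale by 1).
#'
#' @return A named list; see Details for the threshold fields. `paths`
#'   holds input file locations (filled by the caller or by
#'   [simulate_study()]), `out_dir` the output directory, `seed` the RNG
#'   seed used by every stochastic step.
#' @export
default_config <- function() {
  list(
    paths = list(
      eqtl = NULL,             # TSV of cis-eQTL summary stats (with gene, tissue)
      gwas_dir = NULL,         # directory of per-phenotype GWAS TSVs
      affinity = NULL,         # CSV drug,receptor,ki_nM,action,source
      side_effect_map = NULL,  # CSV side_effect,phenotype_id,brain_relevant
      dose_equivalents = NULL, # CSV drug,dose_equivalent
      genes = NULL             # TSV gene,chrom,start,end
    ),
    fdr = 0.05,
    f_min = 22,
    h4_min = 0.6,
    h3_max = 0.1,
    ki_discard_nM = 10000,
    trim = 0.1,
    default_pki = 0.824,
    default_pki_se = 0.15,
    n_boot = 1000,
    cis_window_bp = 1e6,
    nM_to_M = 1e-8,
    coloc_priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
    prior_sd_quant = 0.15,
    prior_sd_binary = 0.2,
    wald_se_method = "first_order",
    on_target = c("DRD2", "DRD3", "DRD4", "HTR2A", "HTR2C"),
    suspected_target = c("GABRA5", "HRH2", "HRH3"),
    brain_tissues = c("basal_ganglia", "cerebellum", "cortex",
                      "hippocampus", "spinal_cord"),
    blood_tissues = "blood",
    genome_build = "GRCh38",
    seed = 1L,
    out_dir = NULL
  )
}

#' Validate a run configuration
#'
#' Checks every threshold against its documented range and reports all
#' violations in one aggregated error, so a bad config fails before any
#' computation starts.
#'
#' @param config A list as returned by [default_config()] (possibly
#'   modified).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(config$fdr) && config$fdr > 0 && config$fdr < 1,
      "fdr must be in (0, 1)")
  chk(num1(config$f_min) && config$f_min >= 0, "f_min must be >= 0")
  chk(num1(config$h4_min) && config$h4_min >= 0 && config$h4_min <= 1,
      "h4_min must be in [0, 1]")
  chk(num1(config$h3_max) && config$h3_max >= 0 && config$h3_max <= 1,
      "h3_max must be in [0, 1]")
  chk(num1(config$ki_discard_nM) && config$ki_discard_nM > 0,
      "ki_discard_nM must be > 0")
  chk(num1(config$trim) && config$trim >= 0 && config$trim < 0.5,
      "trim must be in [0, 0.5)")
  chk(num1(config$default_pki), "default_pki must be a finite number")
  chk(num1(config$default_pki_se) && config$default_pki_se >= 0,
      "default_pki_se must be >= 0")
  chk(num1(config$n_boot) && config$n_boot >= 2,
      "n_boot must be >= 2")
  chk(num1(config$cis_window_bp) && config$cis_window_bp > 0,
      "cis_window_bp must be > 0")
  chk(num1(config$nM_to_M) && config$nM_to_M > 0, "nM_to_M must be > 0")
  for (p in c("p1", "p2", "p12")) {
    v <- config$coloc_priors[[p]]
    chk(num1(v) && v > 0 && v < 1,
        sprintf("coloc prior %s must be in (0, 1)", p))
  }
  chk(num1(config$prior_sd_quant) && config$prior_sd_quant > 0,
      "prior_sd_quant must be > 0")
  chk(num1(config$prior_sd_binary) && config$prior_sd_binary > 0,
      "prior_sd_binary must be > 0")
  chk(config$wald_se_method %in% c("first_order", "second_order"),
      "wald_se_method must be 'first_order' or 'second_order'")

  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' The YAML round-trip is lossless for every scalar field; paths and
#' vector fields are preserved as-is. Fields absent from the file fall
#' back to [default_config()] values.
#'
#' @param path YAML file path.
#' @param config Config list to serialize.
#' @return `read_config()` returns a validated config list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  loaded <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), loaded)
  config$seed <- as.integer(config$seed)
  validate_config(config)
  config
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
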