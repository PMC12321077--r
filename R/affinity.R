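## Binding-affinity summarization: raw multi-lab Ki measurements -> the
## scaled pKi and dose-adjustment quantities the score consumes.

#' Discard weak binding-affinity measurements
#'
#' Drops every measurement at or above the discard threshold (default
#' 10,000 nM): such values indicate no substantial effect on the
#' receptor. Applied per individual measurement, before trimming.
#'
#' @param measurements Numeric vector of Ki values in nM (all > 0).
#' @param threshold Discard boundary in nM; values `>= threshold` are
#'   removed.
#' @return The retained measurements (possibly empty).
#' @export
discard_weak <- function(measurements, threshold = 10000) {
  if (length(measurements) == 0) return(numeric(0))
  stopifnot(is.numeric(measurements), all(measurements > 0))
  measurements[measurements < threshold]
}

#' Trimmed mean with standard error
#'
#' Sorts the values, removes `floor(trim * n)` from each tail (symmetric
#' trimming), and returns the arithmetic mean of the remainder together
#' with its standard error `sd / sqrt(k)` over the `k` surviving values
#' (`se = 0` when `k = 1`). Used to summarize multi-laboratory Ki
#' measurements robustly against outliers.
#'
#' @param values Non-empty numeric vector.
#' @param trim Trimming proportion in `[0, 0.5)`.
#' @return List with `mean`, `se`, and `n_used`.
#' @export
trimmed_mean <- function(values, trim = 0.1) {
  if (length(values) == 0) stop("no measurements", call. = FALSE)
  stopifnot(is.numeric(values), trim >= 0, trim < 0.5)
  n <- length(values)
  k <- floor(trim * n)
  kept <- sort(values)[(k + 1):(n - k)]
  m <- mean(kept)
  se <- if (length(kept) <= 1L) 0 else stats::sd(kept) / sqrt(length(kept))
  list(mean = m, se = se, n_used = length(kept))
}

#' Scale a mean Ki to pKi
#'
#' `pKi = -log10(ki_nM * nM_to_M) - 4`. With the default conversion
#' factor 1e-8 this places pKi between 0 and ~4.5 for measurements in the
#' retained range: Ki = 10,000 nM (the discard boundary) maps to exactly
#' 0 and Ki = 1 nM maps to 4. Strictly decreasing in Ki: stronger binding
#' (smaller Ki) gives larger pKi.
#'
#' @param ki_mean_nM Mean inhibition constant in nM (> 0).
#' @param nM_to_M Conversion factor applied before the log; see
#'   [default_config()].
#' @return pKi (dimensionless).
#' @export
scale_pki <- function(ki_mean_nM, nM_to_M = 1e-8) {
  stopifnot(is.numeric(ki_mean_nM), all(ki_mean_nM > 0))
  -log10(ki_mean_nM * nM_to_M) - 4
}

#' Dose adjustment term
#'
#' `a_d = pKi * log10(de)`: the binding affinity scaled by the log of the
#' drug's dose equivalent. Dose equivalents are centered around 1, so a
#' drug at reference dosing contributes `a_d = 0`.
#'
#' @param pki Scaled binding affinity.
#' @param de Dose equivalent (> 0).
#' @return The adjustment `a_d`.
#' @export
dose_adjustment <- function(pki, de) {
  if (any(!is.finite(de)) || any(de <= 0)) {
    stop("dose equivalent must be > 0", call. = FALSE)
  }
  pki * log10(de)
}

#' Summarize binding affinity for one drug-receptor pair
#'
#' Runs the full measurement pipeline: discard values at or above the
#' 10,000 nM threshold, take the 0.1-trimmed mean of the survivors,
#' convert to molar units and scale to pKi. Three outcomes are
#' distinguished:
#' \itemize{
#'   \item measured: at least one measurement survives; `pki` is computed
#'     from the trimmed mean, `is_default = FALSE`.
#'   \item unmeasured: no measurement exists at all; the configured
#'     default `pki = 0.824 (SE 0.15)` is imputed, `is_default = TRUE`.
#'     Absence of data implies uncertainty, not absence of binding.
#'   \item non-binding: measurements exist but every one is discarded by
#'     the threshold; the pair is excluded from scoring
#'     (`non_binding = TRUE`). Uniformly weak measured binding implies
#'     absence of effect.
#' }
#'
#' @param drug,receptor Labels.
#' @param measurements Numeric vector of Ki in nM (may be empty; NA
#'   entries, from blank table cells, are ignored).
#' @param action Pharmacological action label.
#' @param config Run configuration, see [default_config()].
#' @return One-row `data.frame` with columns `drug, receptor, ki_mean_M,
#'   ki_se_M, pki, pki_se, n_used, action, is_default, non_binding`.
#' @export
summarize_affinity <- function(drug, receptor, measurements,
                               action = "unknown",
                               config = default_config()) {
  meas <- measurements[!is.na(measurements)]
  row <- data.frame(
    drug = drug, receptor = receptor,
    ki_mean_M = NA_real_, ki_se_M = NA_real_,
    pki = NA_real_, pki_se = NA_real_,
    n_used = 0L, action = action,
    is_default = FALSE, non_binding = FALSE,
    stringsAsFactors = FALSE
  )
  if (length(meas) == 0) {
    row$is_default <- TRUE
    row$pki <- config$default_pki
    row$pki_se <- config$default_pki_se
    return(row)
  }
  kept <- discard_weak(meas, config$ki_discard_nM)
  if (length(kept) == 0) {
    row$non_binding <- TRUE
    return(row)
  }
  tm <- trimmed_mean(kept, config$trim)
  row$ki_mean_M <- tm$mean * config$nM_to_M
  row$ki_se_M <- tm$se * config$nM_to_M
  row$pki <- scale_pki(tm$mean, config$nM_to_M)
  ## first-order delta method on -log10: reported for the summary table;
  ## the bootstrap resamples Ki itself rather than using this.
  row$pki_se <- tm$se / (tm$mean * log(10))
  row$n_used <- tm$n_used
  row
}

#' Summarize a full binding-affinity table
#'
#' Applies [summarize_affinity()] to every distinct (drug, receptor) pair
#' in a raw measurement table. When a pair carries several action labels,
#' the modal non-"unknown" label is used.
#'
#' @param affinity Raw table from [read_affinity_table()].
#' @param config Run configuration.
#' @return `data.frame` with one row per pair, columns as in
#'   [summarize_affinity()].
#' @export
summarize_affinity_table <- function(affinity, config = default_config()) {
  key <- paste(affinity$drug, affinity$receptor, sep = "\r")
  out <- lapply(split(seq_len(nrow(affinity)), key), function(idx) {
    sub <- affinity[idx, , drop = FALSE]
    acts <- sub$action[sub$action != "unknown"]
    action <- if (length(acts)) names(sort(table(acts), decreasing = TRUE))[1]
              else "unknown"
    summarize_affinity(sub$drug[1], sub$receptor[1], sub$ki_nM,
                       action, config)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$drug, res$receptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}
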