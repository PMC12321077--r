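## Score assembly: MR estimates x binding affinity x dose equivalents ->
## per (drug, side-effect) scores with parametric-bootstrap SEs.

#' Direction of effect for a pharmacological action
#'
#' Antagonists, inverse agonists and inhibitors reduce receptor
#' signalling, so their contribution is sign-flipped (-1); agonists and
#' positive modulators keep the MR direction (+1). Partial agonists have
#' non-linear binding relationships that preclude a principled sign: they
#' are assigned +1 with a warning, and direction-aware views of their
#' terms should be read with caution. Unknown actions get +1 with a
#' message.
#'
#' @param action Character vector of action labels.
#' @return Numeric vector of +1 / -1.
#' @export
direction_for_action <- function(action) {
  neg <- c("antagonist", "inverse_agonist", "inhibitor")
  if (any(action == "partial_agonist")) {
    warning("partial agonist action: direction assigned +1, ",
            "interpret signed values with caution", call. = FALSE)
  }
  if (any(action == "unknown")) {
    message("unknown action: direction assigned +1")
  }
  ifelse(action %in% neg, -1, 1)
}

#' One score term for a (drug, side-effect, receptor) triple
#'
#' The contribution of one receptor to a drug's side-effect profile:
#' `raw = beta_iv * (pKi + a_d)` with `a_d = pKi * log10(de)`, and
#' `signed_value = direction * raw` where the direction encodes the
#' drug's pharmacological action at the receptor. Non-binding affinity
#' summaries (all measurements discarded) must be excluded upstream --
#' they carry no pKi.
#'
#' @param beta_iv Wald-ratio MR estimate for (receptor, side-effect).
#' @param pki Scaled binding affinity of the drug at the receptor.
#' @param de Dose equivalent of the drug (> 0).
#' @param action Pharmacological action label.
#' @return One-row `data.frame(beta_iv, pki, a_d, direction,
#'   signed_value)`.
#' @export
signed_term <- function(beta_iv, pki, de, action = "unknown") {
  a_d <- dose_adjustment(pki, de)
  direction <- direction_for_action(action)
  raw <- beta_iv * (pki + a_d)
  data.frame(beta_iv = beta_iv, pki = pki, a_d = a_d,
             direction = direction, signed_value = direction * raw)
}

#' Combine score terms for one (drug, side-effect)
#'
#' `score` is the signed sum over the receptor set E that passed every
#' gate; `abs_score` is the sum of absolute term values, the aggregation
#' used for cumulative reporting where the direction of eQTL effects is
#' not relied upon. An empty term list yields a zero entry flagged
#' `no_evidence`.
#'
#' @param terms `data.frame` of score terms sharing one (drug,
#'   side_effect), with a `signed_value` column.
#' @return One-row `data.frame(score, abs_score, n_terms, no_evidence)`.
#' @export
score_side_effect <- function(terms) {
  if (is.null(terms) || nrow(terms) == 0) {
    return(data.frame(score = 0, abs_score = 0, n_terms = 0L,
                      no_evidence = TRUE))
  }
  data.frame(score = sum(terms$signed_value),
             abs_score = sum(abs(terms$signed_value)),
             n_terms = nrow(terms), no_evidence = FALSE)
}

## Internal: evaluate the RNG expression with a locally seeded generator,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Parametric bootstrap of score standard errors
#'
#' Resamples every stochastic input of the score independently and
#' recomputes all (drug, side-effect) entries per iteration:
#' \itemize{
#'   \item each term's `beta_iv ~ Normal(beta_iv, se_iv)`;
#'   \item for measured (drug, receptor) pairs, the mean molar Ki
#'     `~ Normal(ki_mean_M, ki_se_M)` truncated below at 1e-12 M (keeps
#'     the log defined), then re-scaled to pKi;
#'   \item for default-imputed pairs, `pKi ~ Normal(default_pki,
#'     default_pki_se)` directly on the pKi scale.
#' }
#' One affinity draw per (drug, receptor) pair is shared by every term
#' that uses it, so drug-level standard errors (computed from the summed
#' replicates, not from sums of SEs) respect the within-drug dependence
#' on shared affinity draws. The dose adjustment is recomputed from the
#' resampled pKi each iteration. Deterministic given `seed`.
#'
#' @param terms Score-term table with columns `drug, side_effect,
#'   receptor, beta_iv, se_iv, pki, is_default, ki_mean_M, ki_se_M, de,
#'   direction`.
#' @param n_boot Number of bootstrap iterations (>= 2; default 1000).
#' @param seed Integer RNG seed.
#' @param config Run configuration (default pKi and its SE, `nM_to_M`).
#' @return List with `entry` (`drug, side_effect, se_signed, se_abs`),
#'   `drug` (`drug, se_signed, se_abs` for the summed totals) and
#'   `n_boot`.
#' @export
bootstrap_scores <- function(terms, n_boot = 1000, seed = 1,
                             config = default_config()) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  stopifnot(nrow(terms) >= 1)
  with_seed(seed, {
    pair_key <- paste(terms$drug, terms$receptor, sep = "\r")
    pairs <- !duplicated(pair_key)
    ## pKi replicate matrix: one row per unique (drug, receptor) pair
    pki_rep <- matrix(NA_real_, nrow = sum(pairs), ncol = n_boot)
    rownames(pki_rep) <- pair_key[pairs]
    for (k in which(pairs)) {
      key <- pair_key[k]
      if (terms$is_default[k]) {
        pki_rep[key, ] <- stats::rnorm(n_boot, config$default_pki,
                                       config$default_pki_se)
      } else {
        ki <- pmax(stats::rnorm(n_boot, terms$ki_mean_M[k],
                                terms$ki_se_M[k]), 1e-12)
        pki_rep[key, ] <- -log10(ki) - 4
      }
    }
    ## per-term signed replicates: direction * beta * pki * (1 + log10(de))
    term_rep <- matrix(NA_real_, nrow = nrow(terms), ncol = n_boot)
    for (k in seq_len(nrow(terms))) {
      beta <- stats::rnorm(n_boot, terms$beta_iv[k], terms$se_iv[k])
      term_rep[k, ] <- terms$direction[k] * beta * pki_rep[pair_key[k], ] *
        (1 + log10(terms$de[k]))
    }
    entry_key <- paste(terms$drug, terms$side_effect, sep = "\r")
    sd0 <- function(x) if (all(x == x[1])) 0 else stats::sd(x)
    entry_signed <- rowsum(term_rep, entry_key)
    entry_abs <- rowsum(abs(term_rep), entry_key)
    ekeys <- rownames(entry_signed)
    eparts <- strsplit(ekeys, "\r", fixed = TRUE)
    entry <- data.frame(
      drug = vapply(eparts, `[`, "", 1),
      side_effect = vapply(eparts, `[`, "", 2),
      se_signed = apply(entry_signed, 1, sd0),
      se_abs = apply(entry_abs, 1, sd0),
      stringsAsFactors = FALSE, row.names = NULL)
    drug_of_entry <- entry$drug
    drug_signed <- rowsum(entry_signed, drug_of_entry)
    drug_abs <- rowsum(entry_abs, drug_of_entry)
    drug <- data.frame(
      drug = rownames(drug_signed),
      se_signed = apply(drug_signed, 1, sd0),
      se_abs = apply(drug_abs, 1, sd0),
      stringsAsFactors = FALSE, row.names = NULL)
    list(entry = entry, drug = drug, n_boot = n_boot)
  })
}

#' Bootstrap SE of a single score entry
#'
#' Convenience wrapper around [bootstrap_scores()] for the terms of one
#' (drug, side-effect) entry; returns the bootstrap standard error of the
#' signed score. With every input SE equal to zero the result is exactly
#' 0.
#'
#' @inheritParams bootstrap_scores
#' @return Numeric standard error.
#' @export
bootstrap_se <- function(terms, n_boot = 1000, seed = 1,
                         config = default_config()) {
  stopifnot(length(unique(paste(terms$drug, terms$side_effect))) == 1L)
  bootstrap_scores(terms, n_boot = n_boot, seed = seed,
                   config = config)$entry$se_signed[1]
}

#' Aggregate score entries into reporting tables
#'
#' Produces the cumulative views of a run from the score-term table:
#' \itemize{
#'   \item `drug_scores`: per-drug totals, signed and absolute variants,
#'     with the count of side-effects carrying evidence;
#'   \item `receptor_summary`: per (drug, receptor) cumulative absolute
#'     contribution across side-effects;
#'   \item `side_effect_summary`: per (drug, side-effect) signed and
#'     absolute scores;
#'   \item `breakdown`: the full signed term table (per side-effect by
#'     receptor, direction retained);
#'   \item `classification`: per side-effect, the fraction of cumulative
#'     absolute score contributed by on-target or suspected-target
#'     receptors; a side-effect is on-target-dominated when that
#'     fraction exceeds 0.5.
#' }
#' Aggregation conserves mass: the absolute totals of the per-receptor
#' table, the per-side-effect table and the drug totals are identical.
#'
#' @param terms Score-term table (as in [bootstrap_scores()]), with
#'   `signed_value`.
#' @param config Run configuration (`on_target`, `suspected_target`).
#' @return Named list of `data.frame`s as described above.
#' @export
aggregate_scores <- function(terms, config = default_config()) {
  agg <- function(values, by) {
    s <- rowsum(values, by)
    data.frame(key = rownames(s), value = as.numeric(s[, 1]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  split2 <- function(df, nms) {
    parts <- strsplit(df$key, "\r", fixed = TRUE)
    out <- data.frame(a = vapply(parts, `[`, "", 1),
                      b = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
    names(out) <- nms
    out
  }
  if (nrow(terms) == 0) {
    empty <- function(...) {
      x <- data.frame(...)
      x[0, , drop = FALSE]
    }
    return(list(
      drug_scores = empty(drug = "", score = 0, abs_score = 0,
                          n_side_effects = 0L),
      receptor_summary = empty(drug = "", receptor = "", abs_score = 0),
      side_effect_summary = empty(drug = "", side_effect = "", score = 0,
                                  abs_score = 0),
      breakdown = terms,
      classification = empty(side_effect = "", on_target_fraction = 0,
                             dominated_by = "")
    ))
  }

  ekey <- paste(terms$drug, terms$side_effect, sep = "\r")
  se_sum <- agg(terms$signed_value, ekey)
  se_abs <- agg(abs(terms$signed_value), ekey)
  side_effect_summary <- cbind(split2(se_sum, c("drug", "side_effect")),
                               score = se_sum$value,
                               abs_score = se_abs$value)

  rkey <- paste(terms$drug, terms$receptor, sep = "\r")
  r_abs <- agg(abs(terms$signed_value), rkey)
  receptor_summary <- cbind(split2(r_abs, c("drug", "receptor")),
                            abs_score = r_abs$value)

  d_sum <- agg(terms$signed_value, terms$drug)
  d_abs <- agg(abs(terms$signed_value), terms$drug)
  nse <- tapply(side_effect_summary$abs_score > 0,
                side_effect_summary$drug, sum)
  drug_scores <- data.frame(drug = d_sum$key, score = d_sum$value,
                            abs_score = d_abs$value,
                            n_side_effects = as.integer(nse[d_sum$key]),
                            stringsAsFactors = FALSE)

  on_set <- c(config$on_target, config$suspected_target)
  is_on <- terms$receptor %in% on_set
  tot <- agg(abs(terms$signed_value), terms$side_effect)
  on <- rowsum(abs(terms$signed_value) * is_on, terms$side_effect)
  frac <- as.numeric(on[tot$key, 1]) / tot$value
  classification <- data.frame(
    side_effect = tot$key,
    on_target_fraction = frac,
    dominated_by = ifelse(frac > 0.5, "on_target", "off_target"),
    stringsAsFactors = FALSE)

  ord <- function(x, ...) {
    x <- x[do.call(order, list(...)), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  list(
    drug_scores = ord(drug_scores, drug_scores$drug),
    receptor_summary = ord(receptor_summary, receptor_summary$drug,
                           receptor_summary$receptor),
    side_effect_summary = ord(side_effect_summary,
                              side_effect_summary$drug,
                              side_effect_summary$side_effect),
    breakdown = terms,
    classification = ord(classification, classification$side_effect)
  )
}
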