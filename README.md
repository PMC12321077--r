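# sidefxmr

Genetic scoring of on-target and off-target drug side-effects.

Patient-reported side-effects are hard to attribute: is the drug causal,
and if so, through which receptor? `sidefxmr` addresses this for drugs
with many binding targets (the motivating case is antipsychotics, which
bind dozens of dopamine, serotonin, histamine, adrenergic, muscarinic
and GABA receptors) by combining three public data types:

1. **cis-eQTL top hits** that instrument the expression of each receptor
   gene, per tissue (brain regions and blood);
2. **GWAS summary statistics** for phenotypes that proxy reported
   side-effects;
3. **drug–receptor binding affinities** (multi-laboratory Ki
   measurements) with drug dose equivalents.

## The method

For each receptor gene *e* and side-effect-proxy phenotype, the causal
effect of receptor expression is estimated by single-instrument
Mendelian randomization (Wald ratio):

    β_IV = β_ZY / β_ZX,   se(β_IV) = |se_ZY / β_ZX|

where β_ZX is the lead cis-eQTL effect (within ±1 Mb of the gene) and
β_ZY the same SNP's phenotype effect after allele harmonization.
Evidence is gated four ways:

* **instrument strength** — F = (β_ZX/se_ZX)² must exceed 22;
* **multiple testing** — Benjamini–Hochberg FDR < 0.05, applied jointly
  across the phenome-wide screen, then one result per
  side-effect/receptor pair;
* **colocalization** — per-SNP Wakefield approximate Bayes factors over
  the cis locus give posterior probabilities of the five causal
  configurations; a pair is kept only when the shared-causal-variant
  posterior PP.H4 ≥ 0.6 while the distinct-variants posterior
  PP.H3 < 0.1;
* **routing** — brain-relevant side-effects colocalize against brain
  eQTLs, everything else against blood.

Surviving effects are weighted by binding affinity. Per (drug *d*,
receptor *e*): measurements ≥ 10,000 nM are discarded as non-binding,
the rest are summarized by a 0.1-trimmed mean and scaled,

    pKi_e = −log10(K̄i_M) − 4      (K̄i_M = K̄i_nM × 1e−8),

which maps the retained range onto ≈ [0, 4.5]; pairs known to bind but
never measured receive a default pKi of 0.824 (SE 0.15). With dose
equivalents d_e (centered around 1) and a_d = pKi_e · log10(d_e), the
score of drug *d* against side-effect *t* is

    S_d,t = Σ_e  β_IV,e × (pKi_e + a_d)

summed over the receptors *E* that passed every gate, sign-corrected by
the pharmacological action (antagonists and inverse agonists flip).
Standard errors come from a 1000-iteration parametric bootstrap that
resamples β_IV and the affinity inputs, sharing affinity draws across
side-effects of the same drug. Cumulative reporting uses absolute term
values; signed per-term values are always retained for direction-aware
views, and each side-effect is classified as on-target- or
off-target-dominated by whether on/suspected-target receptors
contribute more than 50 % of its cumulative score.

A ground-truth-labelled simulator (`simulate_study()`) generates
complete input bundles — AR(1)-LD loci with planted shared-variant
(H4), distinct-variant (H3) and null scenarios, multi-lab affinity
tables with outliers and missingness — so the entire pipeline is
testable without any data download.

## Worked example

```r
library(sidefxmr)

bundle <- simulate_study(seed = 42, out_dir = "demo/bundle")
config <- default_config()
config$paths  <- bundle$paths
config$out_dir <- "demo/out"
config$seed   <- 42L
res <- run_pipeline(config)

res$drug_scores
#>         drug  score abs_score n_side_effects se_signed se_abs
#> 1  clozapine 0.4693      5.19              4     0.487  0.491
#> 2 olanzapine 0.0129      4.06              4     0.172  0.172

res$entries[res$entries$drug == "clozapine", ]
#>        drug    side_effect  score abs_score se_signed n_terms
#> 1 clozapine blood_pressure -0.567     0.567    0.0881       2
#> 2 clozapine    neutropenia  1.526     1.526    0.1012       1
#> 3 clozapine       sedation -0.938     0.938    0.1659       1
#> 4 clozapine    weight_gain  0.447     2.157    0.4382       2
```

`abs_score` is the cumulative evidence of drug→side-effect causation
through all gated receptors (here clozapine's largest burden is weight
gain, carried by CHRM3 and DRD2 terms); `score` keeps the signed sum,
whose direction should be read cautiously since eQTL and protein
effect directions can disagree. `se_signed` is the bootstrap SE.
`demo/out/` additionally contains the full per-term breakdown
(`scores.tsv`), per-receptor and per-side-effect aggregates, the
on/off-target classification (`classification.tsv`), every intermediate
stage table, and a JSON run manifest. Rerunning with the same config
and seed reproduces every output byte for byte.

A command-line wrapper over the same stages ships in
`inst/cli/sidefxmr.R`:

```sh
Rscript inst/cli/sidefxmr.R simulate --out demo/bundle --seed 42
Rscript inst/cli/sidefxmr.R run --config my_config.yaml --out demo/out
```

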