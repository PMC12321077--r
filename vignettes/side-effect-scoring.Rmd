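---
title: "Scoring drug side-effects with genetic instruments and binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug side-effects with genetic instruments and binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sidefxmr)
```

## The model

`sidefxmr` asks, for every combination of drug, side-effect and
receptor: is there genetic evidence that perturbing this receptor
causes this side-effect, and how strongly does this drug engage the
receptor? The two ingredients are estimated separately and then
composed.

**Causal arm.** Receptor gene expression is instrumented by its lead
cis-eQTL (the smallest-p variant within ±1 Mb of the gene interval, one
per tissue). The causal effect of expression on a side-effect-proxy
phenotype is the single-instrument Wald ratio
$\beta_{IV} = \beta_{ZY} / \beta_{ZX}$, with the first-order
delta-method standard error $|se_{ZY}/\beta_{ZX}|$ (the exposure
uncertainty is second-order when the instrument is strong, which the
F gate guarantees; the second-order form is available behind
`wald_se_method = "second_order"`). This inherits the usual
instrumental-variable assumptions: relevance is enforced by the
F-statistic threshold, while independence and exclusion restriction
cannot be enforced with a single SNP — instead, colocalization is used
as supporting evidence that the eQTL and phenotype associations are
driven by one shared variant rather than two distinct ones in linkage
disequilibrium.

**Affinity arm.** Multi-laboratory Ki measurements for a (drug,
receptor) pair are filtered at the 10,000 nM discard threshold
(values at or above it indicate no substantial receptor engagement),
summarized by a 0.1-trimmed mean, converted and log-scaled:
$pKi = -\log_{10}(\bar{K_i}_M) - 4$. Three outcomes are distinguished
deliberately: *measured* (pKi from data), *unmeasured* (the pair is
known to bind but has no measurement; a default pKi of 0.824, SE 0.15,
is imputed — absence of data means uncertainty), and *non-binding*
(every measurement was discarded — measured absence of effect; the
pair contributes nothing and is logged, not silently zeroed).

**Composition.** With dose equivalent $d_e$ and
$a_d = pKi_e \log_{10}(d_e)$,
$$S_{d,t} = \sum_{e \in E} \beta_{IV,e} \,(pKi_e + a_d),$$
over the receptor set $E$ that passed every gate, each term
sign-corrected by the drug's pharmacological action at the receptor.
Note the algebra collapses to
$\beta_{IV,e}\, pKi_e\,(1 + \log_{10} d_e)$: at reference dosing
($d_e = 1$) the dose path contributes exactly nothing, which the tests
verify.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cis_window_bp` | 1e6 | bp | standard cis definition; also the colocalization region |
| `f_min` | 22 | — | weak-instrument bound for a single instrument |
| `fdr` | 0.05 | — | BH threshold across the whole screen |
| `h4_min` / `h3_max` | 0.6 / 0.1 | posterior prob. | relaxed shared-signal evidence plus a distinct-variant veto (see below) |
| `ki_discard_nM` | 10000 | nM | boundary of "no substantial effect"; maps to pKi = 0 |
| `trim` | 0.1 | proportion | outlier robustness for multi-lab Ki values |
| `default_pki` / `default_pki_se` | 0.824 / 0.15 | pKi | conservative mean affinity for unmeasured binding pairs; taken as a configured constant, not recomputed |
| `nM_to_M` | 1e-8 | — | see "The pKi conversion factor" |
| `coloc_priors` | 1e-4, 1e-4, 1e-5 | per SNP | conventional single-variant priors |
| `prior_sd_quant` / `prior_sd_binary` | 0.15 / 0.2 | effect SD | conventional ABF effect priors (binary traits on the log-odds scale, selected per phenotype via `binary_phenotypes`) |
| `n_boot` | 1000 | iterations | parametric-bootstrap SE |

## Design choices in detail

**The pKi conversion factor.** The conversion applied before the log
is nM × 1e−8, not the physical nM→M factor 1e−9. The 1e−8 factor is
what makes the scale self-consistent: the 10,000 nM discard boundary
lands exactly at pKi = 0 and a strong 1 nM binder at 4, so retained
measurements span ≈ [0, 4.5] and the default 0.824 sits inside the
scale. It is a config constant (`nM_to_M`), so the physical convention
(which shifts every pKi up by 1) can be selected; all scores would
scale accordingly.

**Trimming convention.** "Trimmed mean 0.1" is implemented as the
common symmetric convention: drop `floor(0.1·n)` values from each tail
(matching base R's `mean(x, trim=)`), with the SE of the surviving
values `sd/sqrt(k)`. Note that with fewer than 10 measurements this
trims nothing — for typical 3–8-measurement pairs the 10,000 nM
discard, not the trim, is the operative outlier defence.

**Colocalization.** Per-SNP Wakefield log approximate Bayes factors
($\tfrac12\log\frac{V}{V+W} + \tfrac12 z^2 \frac{W}{V+W}$) are
combined, entirely in log space with log-sum-exp, into the five
single-causal-variant configuration weights (H0 none, H1/H2 one trait
only, H3 two distinct variants, H4 one shared variant). The H4
threshold is inclusive (≥ 0.6): it deliberately sits below the
conventional 0.8 because an under-powered outcome trait can dilute H4
even when the signal is shared, and the H3 < 0.1 veto separates that
situation from genuine distinct-variant loci. A single-SNP locus has
H3 weight exactly zero (no distinct configuration exists). When
several brain tissues pass for one gene, the tissue with the highest
PP.H4 supplies the β_IV entering the score, with the MR q-value as
tie-break; the routing flag (`brain_relevant`) is data carried by the
side-effect map, not an inference. Multi-causal-variant and LD-aware
approaches (SuSiE-style) are out of scope.

**FDR and deduplication.** BH is applied once, jointly, across the
entire screen per run (the screen is a single filtered scan; a
per-phenotype-family alternative would change the effective
threshold). One result is then retained per side-effect/receptor pair;
the tie-break chain — smallest q, then largest F, then
lexicographically smallest SNP id — exists purely to make the
selection deterministic.

**Direction of effect.** Antagonists, inverse agonists and inhibitors
flip the term sign; agonists and positive modulators keep it. Partial
agonists have no principled sign under this linear composition (their
binding relationships are non-linear), so they get +1 with an explicit
warning. Cumulative reporting uses absolute values throughout, since
eQTL and protein-level effect directions are known to disagree for a
substantial fraction of genes; signed values are retained in the
per-term breakdown for direction-aware inspection.

**Bootstrap.** Each iteration independently resamples every term's
β_IV from Normal(β_IV, se_IV) and each (drug, receptor) pair's
affinity — measured pairs on the molar-Ki scale (truncated below at
1e−12 M to keep the log defined, then re-scaled through the pKi
formula so the nonlinearity of the log is propagated, not
linearized), default pairs directly on the pKi scale from
Normal(0.824, 0.15). One affinity draw per pair is shared by every
term that uses it, and drug-level SEs are standard deviations of
summed replicates — not sums of SEs — so within-drug dependence on
shared affinity draws is respected. No β_IV–affinity covariance is
modelled (none is available). Everything is deterministic given the
seed.

## What the simulator emulates — and what it does not

`simulate_study()` generates the five input files plus a truth
manifest. Loci use AR(1) linkage disequilibrium by adjacency
(ρ^|i−j|, default ρ = 0.9), marginal effects equal to the LD row times
the causal-effect vector, and estimate noise with the analytic
standard error $1/\sqrt{2\,maf(1-maf)\,n}$ and LD-correlated errors —
the standard summary-statistic approximation. Planted causal pairs are
shared-variant (H4) loci with eQTL effect 0.3 and causal effect
θ = 0.5 at n = 50,000 for both traits; distinct-variant decoys (H3)
place the two causal variants a third of the locus apart; every other
(gene, phenotype) pair is outcome-null. One point needs stating
explicitly: a literal "H0" locus has no eQTL signal and therefore
never yields an instrument passing F > 22, so the null scenario that
actually calibrates the screen is *exposure-associated,
outcome-null* — that is what the null-calibration test simulates, and
what the outcome-null decoys in the recovery benchmark are. Affinity
tables draw 3–8 log-normal measurements per pair (σ = 0.3 on log10
nM), with order-of-magnitude outliers at rate 0.05 and entire pairs
left unmeasured at rate 0.15, exercising the trimmed-mean and
default-imputation paths. Allele orientation is randomly swapped on
30 % of GWAS rows to exercise harmonization.

Not emulated: real LD panels (block structure, long-range LD), allele
frequency spectra (a single MAF per study), sample overlap between
eQTL and GWAS cohorts, binary-trait liability scaling, population
stratification, and ancestry differences. Passing tests therefore
demonstrate the machinery is correct under its own assumptions — they
do not certify behaviour on real data where those assumptions bend.

## Numerical choices and degenerate inputs

Log-sum-exp throughout colocalization keeps |z| of 60 and beyond
finite. The H3 weight uses `log1p(-exp(d))` on the log-scale
difference d = S12 − S1 − S2, clamped to zero weight when d ≥ 0
(floating-point can push the single-dominant-SNP case marginally
positive). Palindromic (A/T, C/G) variants are dropped rather than
frequency-resolved: with one instrument, a mis-oriented allele flips
the entire causal estimate, so the cost of dropping is small and the
risk of keeping is large. Variant identity is by rsID (the shape of
the intended data sources); positional matching is not attempted.
Empty inputs degrade explicitly: an empty measurement set imputes the
default, an all-discarded set is non-binding, an empty term list is a
zero entry flagged `no_evidence`, an empty score table produces empty
but schema-valid reports.

Test problem sizes: colocalization is verified against exhaustive
enumeration on 500 random loci of up to 10 SNPs (the enumeration
oracle works at direct scale and is only valid for moderate z; the
implementation itself has no such restriction); screen calibration
uses 1,000 null instrument–phenotype pairs; the recovery benchmark
runs the full study design (6 genes × 6 tissues × 50-SNP loci, 5
phenotypes) end to end twice to also check byte-level determinism.

## Limitations

The scores compare drugs, not clinics: they combine lifetime-exposure
eQTL effects with binding affinity and need not translate to clinical
severity, especially where default affinities were imputed. Direction
of effect is unreliable at the single-term level. The single-causal-
variant assumption of the colocalization model is a simplification;
loci with allelic heterogeneity can fail H4 spuriously. Instruments
are cis-eQTLs only — trans effects and protein-level QTLs are out of
scope.
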