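Package: sidefxmr
Title: Genetic Scoring of On-Target and Off-Target Drug Side-Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers causal evidence for drug side-effects from genetics.
    Combines cis-eQTL instruments, GWAS summary statistics for
    side-effect-proxy phenotypes, and multi-source drug-receptor binding
    affinity (Ki) measurements into per drug/side-effect/receptor
    causal-evidence scores. Single-instrument Wald-ratio Mendelian
    randomization with F-statistic and false-discovery-rate gates is
    combined with approximate-Bayes-factor colocalization to retain only
    receptor-phenotype pairs sharing a causal variant; surviving effects
    are weighted by scaled binding affinity (pKi) and dose equivalents,
    and standard errors are propagated by parametric bootstrap. Includes
    a ground-truth-labelled summary-statistic simulator so the whole
    pipeline is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
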