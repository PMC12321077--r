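# Default run configuration: every tunable constant at its standard value.
# Override paths/out_dir per run; CLI flags override file values.
paths:
  eqtl: ~
  gwas_dir: ~
  affinity: ~
  side_effect_map: ~
  dose_equivalents: ~
  genes: ~
fdr: 0.05
f_min: 22
h4_min: 0.6
h3_max: 0.1
ki_discard_nM: 10000
trim: 0.1
default_pki: 0.824
default_pki_se: 0.15
n_boot: 1000
cis_window_bp: 1.0e+06
nM_to_M: 1.0e-08
coloc_priors:
  p1: 1.0e-04
  p2: 1.0e-04
  p12: 1.0e-05
prior_sd_quant: 0.15
prior_sd_binary: 0.2
wald_se_method: first_order
on_target: [DRD2, DRD3, DRD4, HTR2A, HTR2C]
suspected_target: [GABRA5, HRH2, HRH3]
brain_tissues: [basal_ganglia, cerebellum, cortex, hippocampus, spinal_cord]
blood_tissues: [blood]
genome_build: GRCh38
seed: 1
out_dir: ~
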