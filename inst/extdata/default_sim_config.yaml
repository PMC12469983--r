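# Default configuration for the synthetic paired-cohort generator.
# Values mirror the sim_config() defaults: a 5-patient, two-condition
# longitudinal design with per-sample sizes drawn from 1500-3500 cells,
# clonal contraction post-intervention, and six condition-specific
# TRAV-TRBV pairing effects of |log-odds| ln 8.
n_patients: 5
cells_per_sample: null        # null = draw each patient in 1500..3500
usage_concentration: 5.0
patient_noise: 0.05
expanded_fraction_pre: 0.02
expanded_size_range: [6, 100]
contraction_factor: 0.3
persistence_prob: 0.6
cdr3_length_support: [8, 20]
cdr3_length_mode: 14
subset_probs: {CD4: 0.58, CD8: 0.38, Treg: 0.03, other: 0.01}
expanded_cd8_prob: 0.8
seed: 1
pairing_effects:
  trav:      ["TRAV12-2", "TRAV10", "TRAV2",   "TRAV26-2", "TRAV2",   "TRAV26-1"]
  trbv:      ["TRBV14",   "TRBV28", "TRBV6-2", "TRBV7-2",  "TRBV7-2", "TRBV19"]
  log_odds:  [2.0794, 2.0794, 2.0794, 2.0794, 2.0794, 2.0794]   # ln 8
  condition: ["post_GFD", "post_GFD", "pre_GFD", "pre_GFD", "pre_GFD", "pre_GFD"]
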