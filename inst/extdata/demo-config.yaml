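# Demo analysis of a synthetic paired cohort: 15 patients, 200 species-level
# features, 32 planted post-surgery shifts, a planted 2-vs-3 balance driving
# VO2 / recurrence / overall survival, and three planted sign-flipping
# co-abundance correlations.
seed: 1
synthetic:
  n_patients: 15
  n_features: 200
  n_up: 17
  n_down: 15
  delta: 2
  beta: 3
  sigma: 1.5
  flip_rho: 0.8
thresholds:
  min_prevalence: 0.10
  alpha: 0.05
  pseudo_p_alpha: 0.05
  min_abs_rho: 0
  # restrict the flip network to raw-p significant features (the figure
  # convention), rather than the FDR default used everywhere else
  network_restrict_no_fdr: true
permutations:
  permanova: 999
  sparcc: 100
  sparcc_iterations: 20
c_max: 20
cv:
  folds: 5
  repeats: 10
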