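# Example pipeline configuration (all sections optional; defaults apply).
design:
  n_per_group: 10        # fruit per size x storage cell (study scale: 46)
cohort:
  noise_mag_rel_sd: 0.005     # relative sd of magnitude noise
  noise_phase_sd_deg: 0.5     # additive phase noise, degrees
fit:
  enabled: true
  starts: 8
  topology: parallel_electrode
  chi_sq_gate: 3.0e-4
bench:
  families: [svm, lr, mlp, knn, rf, lda, nb, dt]
  repeats: 5
  folds: 10
  train_frac: 0.8
  paper_mode: false      # true: z-score globally before splitting
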