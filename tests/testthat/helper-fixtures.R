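# A small simulated study shared across modeling tests: 5 subjects, 3 throws
# per condition, featurized at the 2 s window. Built once per test run.
tiny_cfg <- simulation_config(n_subjects = 5, throws_per_condition = c(3, 3),
                              seed = 11)
tiny_fm <- build_feature_matrix(tiny_cfg, window_s = 2)

# Single-point hyperparameter grids for fast, deterministic fits.
fast_grids <- list(
  RF = data.frame(ntree = 300, mtry_kind = "sqrt", stringsAsFactors = FALSE),
  SVM_L = data.frame(cost = 1),
  SVM_P = data.frame(cost = 1, degree = 2),
  GBM = data.frame(nrounds = 100, max_depth = 3, eta = 0.1)
)
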