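# Shared fixtures, all generated in code.

# Small well-separated feature table: enough rows per class for SVM
# Platt scaling, cheap enough for repeated fits.
toy_table <- function(n_classes = 3, per_class = 12, n_features = 6,
                      separation = 3, seed = 42) {
  simulate_feature_table(n_classes, per_class, n_features,
                         separation = separation, seed = seed)
}

# Cheap underlying model for tests where the scorer itself is not
# under scrutiny.
rf_spec <- function(ntree = 60, seed = 1) {
  underlying_spec("random_forest", ntree = ntree, seed = seed)
}

# Hand-built cv_result from a p-value matrix, for evaluation-module
# tests that need exact control over the p-values.
fake_cv_result <- function(pvalues, label, fold = rep(1L, nrow(pvalues))) {
  structure(list(pvalues = pvalues, label = factor(label),
                 fold = fold, framework = "icp",
                 spec = underlying_spec("random_forest"),
                 n_folds = length(unique(fold)), seed = 1L),
            class = "cv_result")
}

# Noise-free signature set: closed-form response curves.
clean_signatures <- function(n_classes = 2, n_sensors = 3, seed = 1,
                             separation = 1) {
  make_signatures(n_classes, n_sensors, separation = separation,
                  seed = seed, within_class_cv = 0, noise_sd = 0,
                  drift_slope_sd = 0)
}
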