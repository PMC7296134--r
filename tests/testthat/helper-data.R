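# Shared fixtures built in code.

small_cohort_config <- function(seed = 7, ...) {
  cohort_config(n_controls = 6L, n_patients = 6L, n_regions = 20L,
                lesion_grid = c(12L, 14L, 12L), seed = seed, ...)
}

# Feature matrix with planted within-patient early->late shifts.
# Returns a `feature_matrix` whose first `n_informative` columns shift by
# `d` between phases; per-phase noise sd is 1/sqrt(2) so the paired
# difference has unit sd and `d` is the paired effect size.
planted_feature_matrix <- function(n_patients = 23, n_features = 30,
                                   n_informative = 3, d = 1.2, seed = 1) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n_patients))
  base <- matrix(rnorm(n_patients * n_features), n_patients)
  early <- base + matrix(rnorm(n_patients * n_features, 0, 1 / sqrt(2)),
                         n_patients)
  late <- base + matrix(rnorm(n_patients * n_features, 0, 1 / sqrt(2)),
                        n_patients)
  if (n_informative > 0) {
    late[, seq_len(n_informative)] <- late[, seq_len(n_informative)] + d
  }
  df <- data.frame(subject = rep(pats, 2),
                   timepoint = rep(c("early", "late"), each = n_patients),
                   rbind(early, late), check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("F%02d|metric", seq_len(n_features))
  standardize_features(df)
}

# Delta dataset with planted coefficients on the first predictors.
planted_delta_dataset <- function(n = 23, betas = c(2, -1), n_null = 5,
                                  noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  p <- length(betas) + n_null
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- sprintf("X%02d|metric", seq_len(p))
  y <- as.vector(X[, seq_along(betas), drop = FALSE] %*% betas) +
    rnorm(n, 0, noise_sd)
  structure(list(x = X, y = y, patient_id = sprintf("P%02d", seq_len(n))),
            class = "delta_dataset")
}
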