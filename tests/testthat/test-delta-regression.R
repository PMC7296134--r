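# Change-score regression: deltas, OLS fit, VIF, backward elimination,
# residual diagnostics.

test_that("deltas are late minus early and antisymmetric under phase swap", {
  fm <- planted_feature_matrix(n_patients = 5, n_features = 4, seed = 3)
  cfc_sc <- data.frame(
    subject_id = rep(sprintf("P%02d", 1:5), 2),
    timepoint = rep(c("early", "late"), each = 5),
    cfc = c(1:5, c(3, 3, 3, 3, 3)), stringsAsFactors = FALSE)
  feats <- colnames(fm$x)[1:2]
  dd <- compute_deltas(fm, cfc_sc, feats)
  pr <- netrecov:::paired_rows(fm)
  expect_equal(unname(dd$x),
               unname(fm$x[pr$late, feats] - fm$x[pr$early, feats]))
  expect_equal(dd$y, c(3, 3, 3, 3, 3) - 1:5)
  # swap phases -> every delta negated
  fm2 <- fm
  fm2$timepoint <- ifelse(fm$timepoint == "early", "late", "early")
  cfc2 <- cfc_sc
  cfc2$timepoint <- ifelse(cfc_sc$timepoint == "early", "late", "early")
  dd2 <- compute_deltas(fm2, cfc2, feats)
  expect_equal(dd2$x, -dd$x)
  expect_equal(dd2$y, -dd$y)
  # identical phases -> all-zero deltas
  fm3 <- fm
  fm3$x[pr$late, ] <- fm3$x[pr$early, ]
  cfc3 <- cfc_sc; cfc3$cfc <- rep(1:5, 2)
  dd3 <- compute_deltas(fm3, cfc3, feats)
  expect_true(all(dd3$x == 0) && all(dd3$y == 0))
})

test_that("a noiseless planted model is recovered exactly", {
  dd <- planted_delta_dataset(n = 23, betas = c(2, -1), n_null = 0,
                              noise_sd = 0, seed = 4)
  m <- suppressWarnings(fit_delta_model(dd))  # R warns on perfect fits
  expect_equal(unname(m$coefficients[c("X01|metric", "X02|metric")]),
               c(2, -1), tolerance = 1e-8)
  expect_equal(m$adj_r2, 1, tolerance = 1e-8)
  expect_equal(m$nrmse, 0, tolerance = 1e-8)
  expect_true(all(abs(m$residuals) < 1e-8))
})

test_that("adjusted R2 matches its closed form and the F-test is null-calibrated", {
  dd <- planted_delta_dataset(n = 20, betas = c(1), n_null = 2,
                              noise_sd = 1, seed = 5)
  m <- fit_delta_model(dd)
  n <- 20; p <- 3
  expect_equal(m$adj_r2, 1 - (1 - m$r2) * (n - 1) / (n - p - 1))
  # null simulation: F-test p-values uniform
  set.seed(6)
  pvals <- replicate(400, {
    X <- matrix(rnorm(23 * 3), 23)
    colnames(X) <- paste0("x", 1:3)
    dd0 <- structure(list(x = X, y = rnorm(23),
                          patient_id = sprintf("P%02d", 1:23)),
                     class = "delta_dataset")
    fit_delta_model(dd0)$f_p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("affine equivariance: scaling the outcome scales coefficients only", {
  dd <- planted_delta_dataset(n = 23, betas = c(1.5, -0.5), n_null = 2,
                              noise_sd = 0.3, seed = 7)
  m1 <- fit_delta_model(dd)
  dd2 <- dd; dd2$y <- 3 * dd$y
  m2 <- fit_delta_model(dd2)
  expect_equal(m2$coefficients, 3 * m1$coefficients)
  expect_equal(m2$adj_r2, m1$adj_r2)
  expect_equal(m2$nrmse, m1$nrmse)
  expect_equal(m2$f_p_value, m1$f_p_value)
})

test_that("standardized coefficients reproduce the z-scored fit ordering", {
  dd <- planted_delta_dataset(n = 23, betas = c(2, -1, 0.5), n_null = 1,
                              noise_sd = 0.2, seed = 8)
  m <- fit_delta_model(dd)
  ddz <- dd
  ddz$x <- scale(dd$x)[, ]
  ddz$y <- as.vector(scale(dd$y))
  mz <- fit_delta_model(ddz)
  bz <- mz$coefficients[colnames(dd$x)]
  expect_equal(unname(m$std_coefficients[colnames(dd$x)]), unname(bz),
               tolerance = 1e-10)
  expect_equal(order(abs(m$std_coefficients)), order(abs(bz)))
})

test_that("VIF has its closed forms and flags exact collinearity", {
  set.seed(9)
  # exactly uncorrelated design (principal component scores)
  Q <- prcomp(matrix(rnorm(100 * 3), 100))$x
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  # planted correlation r = 0.8 -> VIF ~ 1/(1-0.64)
  x1 <- rnorm(200)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(200)
  V <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(V[1]), 1 / (1 - 0.64), tolerance = 0.2)
  # cross-check against the standard regression-diagnostics implementation
  y <- rnorm(200)
  fit <- lm(y ~ x1 + x2)
  expect_equal(unname(vif(cbind(x1 = x1, x2 = x2))),
               unname(car::vif(fit)), tolerance = 1e-8)
  expect_error(vif(cbind(a = x1, b = 2 * x1)),
               class = "netrecov_collinear_error")
  dup <- planted_delta_dataset(n = 20, betas = c(1), n_null = 1, seed = 10)
  dup$x <- cbind(dup$x, `X03|dup` = dup$x[, 1])
  expect_error(fit_delta_model(dup), class = "netrecov_collinear_error")
})

test_that("backward elimination always keeps strong predictors and prunes most noise", {
  # With |beta| = 1 and noise sd 0.05 the planted predictors are never
  # dropped. A spurious null can survive only by being significant at the
  # final stage; the survivor behaves like the minimum of the 5 null
  # p-values, so the exact-recovery rate is expected near
  # 1 - (1 - 0.95^5) ~ 0.77. Assert recall 1 and a floor 4 binomial sds
  # below that expectation.
  res <- vapply(1:100, function(s) {
    dd <- planted_delta_dataset(n = 23, betas = c(1, -1), n_null = 5,
                                noise_sd = 0.05, seed = 3000 + s)
    m <- backward_eliminate(dd)
    c(recall = all(c("X01|metric", "X02|metric") %in% m$features),
      exact = setequal(m$features, c("X01|metric", "X02|metric")))
  }, c(recall = NA, exact = NA))
  expect_equal(mean(res["recall", ]), 1)
  expect_gte(mean(res["exact", ]), 0.60)
})

test_that("elimination is a fixed point on significant models and terminates on noise", {
  dd <- planted_delta_dataset(n = 23, betas = c(2, -1), n_null = 0,
                              noise_sd = 0.05, seed = 11)
  m <- backward_eliminate(dd)
  expect_setequal(m$features, colnames(dd$x))
  expect_equal(nrow(m$trace), 0)
  expect_true(m$significant)
  # pure noise: terminates, with an empty or flagged final set
  dd0 <- planted_delta_dataset(n = 23, betas = numeric(0), n_null = 6,
                               noise_sd = 1, seed = 12)
  dd0$y <- rnorm(23)
  m0 <- backward_eliminate(dd0)
  expect_true(length(m0$features) == 0 || m0$significant)
  expect_lte(nrow(m0$trace), 6)
  if (nrow(m0$trace) > 0) {
    expect_equal(m0$trace$step, seq_len(nrow(m0$trace)))
    expect_equal(anyDuplicated(m0$trace$dropped), 0)
  }
})

test_that("residual diagnostics have OLS properties and the right shapes", {
  dd <- planted_delta_dataset(n = 20, betas = c(1), n_null = 2,
                              noise_sd = 0.5, seed = 13)
  m <- fit_delta_model(dd)
  diag <- residual_diagnostics(m)
  expect_equal(sum(m$residuals), 0, tolerance = 1e-10)
  expect_equal(nrow(diag$residuals_vs_fitted), 20)
  expect_equal(nrow(diag$lag), 19)
  expect_equal(nrow(diag$qq), 20)
  expect_true(diag$shapiro_p >= 0 && diag$shapiro_p <= 1)
  # noiseless fit: all residuals zero
  dd0 <- planted_delta_dataset(n = 15, betas = c(1, 2), n_null = 0,
                               noise_sd = 0, seed = 14)
  m0 <- suppressWarnings(fit_delta_model(dd0))
  expect_true(all(abs(m0$residuals) < 1e-10))
})
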