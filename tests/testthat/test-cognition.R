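# Score transformation, CFC derivation and group comparisons.

test_that("z-skewness matches the direct formula and its symmetries", {
  expect_equal(z_skewness(c(-2, -1, 0, 1, 2)), 0)
  set.seed(4)
  x <- rlnorm(30)
  expect_equal(z_skewness(-x), -z_skewness(x))
  # direct evaluation on a fixed 20-point sample
  x20 <- c(0.3, 0.5, 0.7, 0.8, 1.1, 1.2, 1.4, 1.5, 1.7, 2.0,
           2.2, 2.5, 2.7, 3.1, 3.6, 4.2, 5.0, 6.1, 7.9, 11.4)
  n <- 20
  m <- mean(x20)
  g1 <- mean((x20 - m)^3) / mean((x20 - m)^2)^1.5
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  expect_equal(z_skewness(x20), g1 / se)
  expect_error(z_skewness(c(1, 2)), "at least 3")
  expect_error(z_skewness(rep(1, 10)), "constant")
})

test_that("Box-Cox has the right closed forms and normalizes log-normal data", {
  x <- c(0.5, 1, 2, 4, 9)
  expect_equal(boxcox_transform(x, lambda = 1)$y, x - 1)
  expect_equal(boxcox_transform(x, lambda = 0)$y, log(x))
  # shift recorded for non-positive input
  tr <- boxcox_transform(c(-1, 0, 2, 3), lambda = 1)
  expect_equal(tr$shift, 2)
  # ML lambda agrees with the profile-likelihood grid in MASS
  set.seed(9)
  z <- rlnorm(150, 1, 0.6)
  bc <- MASS::boxcox(z ~ 1, lambda = seq(-1, 1.5, 0.005), plotit = FALSE)
  expect_equal(boxcox_transform(z)$lambda, bc$x[which.max(bc$y)],
               tolerance = 0.01)
  # de-skewing works with high probability
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rlnorm(200, 0, 0.8)
    abs(z_skewness(boxcox_transform(x)$y)) < 1.96
  }, NA)
  expect_gte(mean(ok), 0.95)
})

one_factor_scores <- function(n = 100, loadings = c(0.9, 0.8, 0.7, 0.6),
                              noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  ability <- rnorm(n)
  X <- sapply(loadings, function(l) l * ability + rnorm(n, 0, noise_sd))
  colnames(X) <- paste0("test", seq_along(loadings))
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             timepoint = "early", X, stringsAsFactors = FALSE)
}

test_that("CFC recovers a planted one-factor structure", {
  loadings <- c(0.9, 0.8, 0.7, 0.6)
  sc <- one_factor_scores(100, loadings, noise_sd = 0.2, seed = 42)
  res <- derive_cfc(sc, tests = paste0("test", 1:4),
                    polarity = c(test1 = 1, test2 = 1, test3 = 1, test4 = 1))
  expect_equal(sum(res$loadings^2), 1)
  cosine <- sum(res$loadings * loadings) /
    sqrt(sum(loadings^2))
  expect_gt(abs(cosine), 0.95)
  expect_equal(sum(res$explained_variance_ratio), 1)
})

test_that("rank-1 input yields a single component explaining all variance", {
  set.seed(5)
  a <- rnorm(40)
  sc <- data.frame(subject_id = sprintf("S%02d", 1:40), timepoint = "early",
                   t1 = 2 * a + 1, t2 = -3 * a, t3 = 0.5 * a, t4 = a,
                   stringsAsFactors = FALSE)
  res <- derive_cfc(sc, tests = c("t1", "t2", "t3", "t4"),
                    polarity = c(t1 = 1, t2 = 1, t3 = 1, t4 = 1))
  expect_equal(res$explained_variance_ratio[1], 1)
})

test_that("orientation puts controls at or above early patients", {
  set.seed(6)
  nC <- 15; nP <- 12
  ability <- c(rnorm(nC, 1), rnorm(nP, -1))
  X <- sapply(1:4, function(j) 0.8 * ability + rnorm(nC + nP, 0, 0.3))
  colnames(X) <- paste0("t", 1:4)
  sc <- data.frame(subject_id = sprintf("S%02d", seq_len(nC + nP)),
                   timepoint = rep(c("control", "early"), c(nC, nP)), X,
                   stringsAsFactors = FALSE)
  res <- derive_cfc(sc, tests = paste0("t", 1:4),
                    polarity = setNames(rep(1, 4), paste0("t", 1:4)))
  m <- tapply(res$scores$cfc, res$scores$timepoint, mean)
  expect_gte(m["control"], m["early"])
})

test_that("CFC is invariant to subject and test reordering", {
  ds <- generate_cohort(small_cohort_config(seed = 13))
  res <- derive_cfc(ds$scores)
  perm <- sample(nrow(ds$scores))
  sc2 <- ds$scores[perm, c("subject_id", "timepoint",
                           rev(netrecov:::COG_TESTS))]
  res2 <- derive_cfc(sc2)
  m1 <- res$scores[order(res$scores$subject_id, res$scores$timepoint), ]
  m2 <- res2$scores[order(res2$scores$subject_id, res2$scores$timepoint), ]
  expect_equal(m2$cfc, m1$cfc, tolerance = 1e-10)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(8)
  for (m in 2:6) {
    for (rep in 1:20) {
      p <- runif(m)
      expect_equal(bh_adjust(p), oracle_bh(p))
    }
  }
})

test_that("group comparisons gate on normality and adjust with BH", {
  ds <- generate_cohort(cohort_config(n_controls = 28, n_patients = 23,
                                      n_regions = 8,
                                      lesion_grid = c(8, 8, 8), seed = 21))
  res <- compare_cfc_groups(derive_cfc(ds$scores))
  expect_setequal(res$comparison,
                  c("early_vs_control", "late_vs_control", "early_vs_late"))
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
  # planted deficit: early patients below controls, significant
  expect_lt(res$p_adjusted[res$comparison == "early_vs_control"], 0.05)

  # heavily skewed inputs should trigger the rank-based test
  set.seed(30)
  n <- 20
  cfc_sc <- data.frame(
    subject_id = c(sprintf("C%02d", 1:n), rep(sprintf("P%02d", 1:n), 2)),
    timepoint = rep(c("control", "early", "late"), each = n),
    cfc = c(rlnorm(n, 0, 1.5)^2, rlnorm(n, -1, 1.5)^2, rlnorm(n, 0, 1.5)^2),
    stringsAsFactors = FALSE)
  res2 <- compare_cfc_groups(cfc_sc)
  expect_true(res2$test[res2$comparison == "early_vs_control"] %in%
                c("Mann-Whitney U"))
})

test_that("planted early-vs-control shifts are detected reliably", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    nC <- 28; nP <- 23
    cfc_sc <- data.frame(
      subject_id = c(sprintf("C%02d", 1:nC), rep(sprintf("P%02d", 1:nP), 2)),
      timepoint = rep(c("control", "early", "late"), c(nC, nP, nP)),
      cfc = c(rnorm(nC, 0), rnorm(nP, -2), rnorm(nP, 0)),
      stringsAsFactors = FALSE)
    res <- compare_cfc_groups(cfc_sc)
    res$p_adjusted[res$comparison == "early_vs_control"] < 0.05
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("unpaired early/late subjects are rejected", {
  sc <- data.frame(subject_id = c("A", "B", "A", "C"),
                   timepoint = c("early", "early", "late", "late"),
                   cfc = rnorm(4), stringsAsFactors = FALSE)
  expect_error(compare_cfc_groups(sc), "paired")
})
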