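# Cognitive function component (CFC): neuropsychological score
# transformation, PCA composite, and group comparisons.

#' z-skewness of a sample
#'
#' Sample skewness g1 divided by its standard error
#' sqrt(6n(n-1) / ((n-2)(n+1)(n+3))). Values beyond +/-1.96 indicate
#' significant skew at the 5% level.
#'
#' @param x Numeric sample, n >= 3, non-constant.
#' @return Scalar z-skewness.
#' @export
z_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) abort_netrecov("z-skewness needs at least 3 observations",
                            "netrecov_stat_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort_netrecov("z-skewness undefined for constant sample",
                              "netrecov_stat_error")
  g1 <- mean((x - m)^3) / m2^1.5
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  g1 / se
}

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' Finds the power parameter by maximizing the profile log-likelihood of
#' the one-sample normal model and returns
#' \eqn{y = (x^\lambda - 1)/\lambda} (log x at \eqn{\lambda = 0}).
#' Non-positive inputs are first shifted by `-min(x) + 1`, with the shift
#' recorded.
#'
#' @param x Numeric sample, non-constant.
#' @param lambda Optional fixed lambda; when `NULL` it is estimated.
#' @param interval Search interval for the ML estimate.
#' @return List with `y` (transformed sample), `lambda` and `shift`.
#' @export
boxcox_transform <- function(x, lambda = NULL, interval = c(-5, 5)) {
  if (stats::sd(x) == 0) abort_netrecov("Box-Cox undefined for constant input",
                                        "netrecov_stat_error")
  shift <- 0
  if (min(x) <= 0) {
    shift <- -min(x) + 1
    x <- x + shift
  }
  bc <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  if (is.null(lambda)) {
    n <- length(x)
    loglik <- function(l) {
      y <- bc(l)
      -n / 2 * log(stats::var(y) * (n - 1) / n) + (l - 1) * sum(log(x))
    }
    lambda <- stats::optimize(loglik, interval, maximum = TRUE)$maximum
  }
  list(y = bc(lambda), lambda = lambda, shift = shift)
}

#' Derive the cognitive function component (CFC)
#'
#' Applies the test polarity map (so higher always means better), Box-Cox
#' transforms tests whose |z-skewness| exceeds `skew_threshold`,
#' standardizes every test, and fits a PCA on the pooled sample (controls
#' plus both patient phases). The CFC is the first-component score,
#' sign-oriented so that the control mean is at least the early-patient
#' mean (falling back to positive correlation with the mean standardized
#' score when no controls are present).
#'
#' @param scores Data frame with `subject_id`, `timepoint`
#'   (control/early/late) and one column per test.
#' @param tests Character vector of test columns entering the PCA.
#' @param polarity Named vector of +/-1 multipliers per test (timed tests
#'   where lower is better get -1).
#' @param skew_threshold |z-skewness| above which a test is Box-Cox
#'   transformed.
#' @return Object of class `cfc_result`: Box-Cox lambdas and shifts,
#'   standardization parameters, unit-norm loadings, explained-variance
#'   ratios, orientation sign, and a `scores` data frame of per
#'   subject-timepoint CFC values.
#' @export
derive_cfc <- function(scores, tests = COG_TESTS,
                       polarity = DEFAULT_POLARITY,
                       skew_threshold = 1.96) {
  stopifnot(all(c("subject_id", "timepoint") %in% names(scores)))
  tests <- intersect(tests, names(scores))
  if (length(tests) < 2) abort_netrecov("CFC needs at least 2 tests",
                                        "netrecov_stat_error")
  if (anyDuplicated(scores[c("subject_id", "timepoint")])) {
    abort_netrecov("duplicated (subject, timepoint) rows",
                   "netrecov_stat_error")
  }
  X <- as.matrix(scores[tests])
  if (anyNA(X)) abort_netrecov("tests entering the PCA must be complete",
                               "netrecov_stat_error")
  pol <- polarity[tests]
  pol[is.na(pol)] <- 1
  X <- sweep(X, 2, pol, "*")

  lambdas <- stats::setNames(rep(NA_real_, length(tests)), tests)
  shifts <- stats::setNames(rep(0, length(tests)), tests)
  for (j in seq_along(tests)) {
    if (abs(z_skewness(X[, j])) > skew_threshold) {
      tr <- boxcox_transform(X[, j])
      X[, j] <- tr$y
      lambdas[j] <- tr$lambda
      shifts[j] <- tr$shift
    }
  }
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) abort_netrecov(
    sprintf("constant test column: %s", paste(tests[scl == 0], collapse = ", ")),
    "netrecov_stat_error")
  Z <- scale(X, center = center, scale = scl)

  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  loadings <- pca$rotation[, 1]
  cfc <- as.vector(Z %*% loadings)

  is_control <- scores$timepoint == "control"
  is_early <- scores$timepoint == "early"
  if (any(is_control) && any(is_early)) {
    sign_ok <- mean(cfc[is_control]) >= mean(cfc[is_early])
  } else {
    sign_ok <- stats::cor(cfc, rowMeans(Z)) >= 0
  }
  orientation_sign <- if (sign_ok) 1 else -1
  cfc <- orientation_sign * cfc
  loadings <- orientation_sign * loadings

  structure(list(
    tests = tests, polarity = pol, lambdas = lambdas, shifts = shifts,
    center = center, scale = scl, loadings = loadings,
    explained_variance_ratio = evr, orientation_sign = orientation_sign,
    scores = data.frame(subject_id = scores$subject_id,
                        timepoint = scores$timepoint, cfc = cfc,
                        stringsAsFactors = FALSE)
  ), class = "cfc_result")
}

# Normality-gated two-sample comparison. Paired tests gate on the
# Shapiro-Wilk p of the differences; unpaired tests on both samples.
#' @keywords internal
#' @noRd
gated_test <- function(x, y, paired, alpha = 0.05) {
  shapiro_ok <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  if (paired) {
    normal <- shapiro_ok(x - y)
    if (normal) {
      ht <- stats::t.test(x, y, paired = TRUE)
      name <- "paired t-test"
    } else {
      ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      name <- "Wilcoxon signed-rank"
    }
  } else {
    normal <- shapiro_ok(x) && shapiro_ok(y)
    if (normal) {
      ht <- stats::t.test(x, y)
      name <- "independent t-test"
    } else {
      ht <- stats::wilcox.test(x, y, exact = FALSE)
      name <- "Mann-Whitney U"
    }
  }
  list(test = name, statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare CFC between groups and phases
#'
#' Three comparisons: early vs control, late vs control (independent) and
#' early vs late (paired by subject). The parametric test (t) is used when
#' Shapiro-Wilk accepts normality at the 5% level, otherwise the rank
#' test (Mann-Whitney U / Wilcoxon signed-rank). P-values are
#' Benjamini-Hochberg adjusted across the three comparisons.
#'
#' @param cfc A `cfc_result` (or its `scores` data frame).
#' @return Data frame with comparison, test name, statistic, raw and
#'   FDR-adjusted p-values.
#' @export
compare_cfc_groups <- function(cfc) {
  sc <- if (inherits(cfc, "cfc_result")) cfc$scores else cfc
  ctrl <- sc$cfc[sc$timepoint == "control"]
  early <- sc[sc$timepoint == "early", ]
  late <- sc[sc$timepoint == "late", ]
  if (!setequal(early$subject_id, late$subject_id)) {
    abort_netrecov("early/late subjects are not fully paired",
                   "netrecov_stat_error")
  }
  late <- late[match(early$subject_id, late$subject_id), ]

  res <- list(
    early_vs_control = gated_test(early$cfc, ctrl, paired = FALSE),
    late_vs_control = gated_test(late$cfc, ctrl, paired = FALSE),
    early_vs_late = gated_test(early$cfc, late$cfc, paired = TRUE)
  )
  out <- data.frame(
    comparison = names(res),
    test = vapply(res, `[[`, "", "test"),
    statistic = vapply(res, `[[`, 0, "statistic"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of raw p-values.
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
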