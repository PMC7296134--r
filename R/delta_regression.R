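# Linear model of cognitive change on changes in selected network
# metrics: dY = b0 + b1 dX1 + ... + bN dXN, with backward elimination,
# variance-inflation diagnostics, and residual inspection.

#' Late-minus-early change dataset
#'
#' Element-wise late - early differences, per patient, of the
#' standardized selected features and of the CFC.
#'
#' @param fm A `feature_matrix` with early and late rows.
#' @param cfc A `cfc_result` (or its `scores` data frame).
#' @param features Character vector of feature names (or a
#'   `selected_features` object).
#' @return Object of class `delta_dataset`: list with matrix `x`
#'   (patients x features), numeric `y` (delta CFC) and `patient_id`.
#' @export
compute_deltas <- function(fm, cfc, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (inherits(features, "selected_features")) features <- features$features$feature
  sc <- if (inherits(cfc, "cfc_result")) cfc$scores else cfc
  pr <- paired_rows(fm)
  pats <- fm$subject[pr$early]
  dx <- fm$x[pr$late, features, drop = FALSE] -
    fm$x[pr$early, features, drop = FALSE]
  rownames(dx) <- pats
  ce <- sc$cfc[sc$timepoint == "early"][match(pats, sc$subject_id[sc$timepoint == "early"])]
  cl <- sc$cfc[sc$timepoint == "late"][match(pats, sc$subject_id[sc$timepoint == "late"])]
  if (anyNA(ce) || anyNA(cl)) abort_netrecov(
    "missing early or late CFC for some patients", "netrecov_stat_error")
  structure(list(x = dx, y = cl - ce, patient_id = pats),
            class = "delta_dataset")
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R_j^2) from regressing predictor j on the remaining
#' predictors. Values of 10 or more flag multicollinearity.
#'
#' @param X Numeric design matrix (at least 2 columns).
#' @return Named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) abort_netrecov("VIF needs at least 2 predictors",
                            "netrecov_stat_error")
  out <- stats::setNames(numeric(p), colnames(X) %||% paste0("x", seq_len(p)))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) abort_netrecov(
      sprintf("predictor '%s' is perfectly collinear with the others",
              names(out)[j]), "netrecov_collinear_error")
    out[j] <- 1 / (1 - r2)
  }
  out
}

#' Fit the change-score linear model
#'
#' Ordinary least squares of delta CFC on the delta features, with
#' adjusted R^2, nRMSE (RMSE divided by the observed range of the
#' outcome), the F-test against the intercept-only model, standardized
#' coefficients (beta_j sd(x_j)/sd(y), the importance ranking), and VIFs
#' of the retained predictors.
#'
#' @param dd A `delta_dataset`.
#' @param features Features to include; default all columns of `dd$x`.
#' @return Object of class `delta_model`.
#' @export
fit_delta_model <- function(dd, features = colnames(dd$x)) {
  stopifnot(inherits(dd, "delta_dataset"))
  X <- dd$x[, features, drop = FALSE]
  y <- dd$y
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort_netrecov(
    sprintf("need more rows (%d) than predictors + 1 (%d)", n, p + 1),
    "netrecov_stat_error")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    bad <- features[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1]
    abort_netrecov(sprintf("singular design matrix; collinear column(s): %s",
                           paste(bad, collapse = ", ")),
                   "netrecov_collinear_error")
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste0(".y ~ ", paste0("`", features, "`",
                                                  collapse = " + ")))
  if (p == 0) fml <- stats::as.formula(".y ~ 1")
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)

  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", features)[seq_along(coefs)]
  pvals <- sm$coefficients[, "Pr(>|t|)"]
  names(pvals) <- names(coefs)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  rng <- diff(range(y))
  nrmse <- if (rng > 0) rmse / rng else 0
  if (p > 0) {
    fstat <- sm$fstatistic
    f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    std_coef <- coefs[features] * apply(X, 2, stats::sd) / stats::sd(y)
    vifs <- if (p >= 2) vif(X) else stats::setNames(1, features)
  } else {
    fstat <- c(value = NA_real_); f_p <- NA_real_
    std_coef <- numeric(0); vifs <- numeric(0)
  }
  structure(list(
    coefficients = coefs, p_values = pvals,
    std_coefficients = std_coef, adj_r2 = sm$adj.r.squared,
    r2 = sm$r.squared, nrmse = nrmse,
    f_statistic = unname(fstat[1]), f_p_value = unname(f_p),
    vif = vifs, residuals = unname(res), fitted = unname(stats::fitted(fit)),
    features = features, n = n, lm = fit
  ), class = "delta_model")
}

#' Backward elimination of predictors
#'
#' Iteratively refits, discarding at each round the predictor with the
#' highest p-value, until every coefficient and the model F-test are
#' significant at `alpha`. If all predictors are eliminated the
#' intercept-only result is returned, flagged non-significant.
#'
#' @param dd A `delta_dataset`.
#' @param features Starting predictor set; default all.
#' @param alpha Significance level for coefficients and the F-test.
#' @return The final `delta_model`, with an elimination `trace` data
#'   frame and a `significant` flag attached as list elements.
#' @export
backward_eliminate <- function(dd, features = colnames(dd$x), alpha = 0.05) {
  current <- features
  n <- length(dd$y)
  if (length(current) > n - 2) {
    # saturated design: keep the leading (highest-ranked) feasible subset
    warning(sprintf(
      "%d predictors cannot start elimination with %d rows; keeping the first %d",
      length(current), n, n - 2))
    current <- current[seq_len(n - 2)]
  }
  trace <- list()
  step <- 0
  repeat {
    if (length(current) == 0) {
      model <- intercept_only_model(dd)
      model$significant <- FALSE
      model$trace <- do.call(rbind, trace) %||%
        data.frame(step = integer(), dropped = character(),
                   p_value = numeric(), adj_r2 = numeric(),
                   f_p_value = numeric())
      return(model)
    }
    model <- fit_delta_model(dd, current)
    coef_p <- model$p_values[current]
    ok <- all(coef_p < alpha) && model$f_p_value < alpha
    if (ok) {
      model$significant <- TRUE
      model$trace <- do.call(rbind, trace) %||%
        data.frame(step = integer(), dropped = character(),
                   p_value = numeric(), adj_r2 = numeric(),
                   f_p_value = numeric())
      return(model)
    }
    worst <- names(which.max(coef_p))
    step <- step + 1
    trace[[step]] <- data.frame(step = step, dropped = worst,
                                p_value = unname(coef_p[worst]),
                                adj_r2 = model$adj_r2,
                                f_p_value = model$f_p_value,
                                stringsAsFactors = FALSE)
    current <- setdiff(current, worst)
  }
}

#' @keywords internal
#' @noRd
intercept_only_model <- function(dd) {
  y <- dd$y
  res <- y - mean(y)
  rng <- diff(range(y))
  structure(list(
    coefficients = c(`(Intercept)` = mean(y)),
    p_values = c(`(Intercept)` = NA_real_),
    std_coefficients = numeric(0), adj_r2 = 0, r2 = 0,
    nrmse = if (rng > 0) sqrt(mean(res^2)) / rng else 0,
    f_statistic = NA_real_, f_p_value = NA_real_, vif = numeric(0),
    residuals = unname(res), fitted = rep(mean(y), length(y)),
    features = character(0), n = length(y), lm = NULL
  ), class = "delta_model")
}

#' Residual diagnostics bundle
#'
#' Data for the three standard residual plots (residuals vs fitted,
#' lag-1 residual pairs, normal quantile-quantile) plus a Shapiro-Wilk
#' test of residual normality. No plotting is performed.
#'
#' @param model A `delta_model`.
#' @return List with data frames `residuals_vs_fitted` (n rows), `lag`
#'   (n-1 rows), `qq` (n rows) and `shapiro_p`.
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "delta_model"))
  r <- model$residuals
  n <- length(r)
  qq <- stats::qqnorm(r, plot.it = FALSE)
  list(
    residuals_vs_fitted = data.frame(fitted = model$fitted, residual = r),
    lag = data.frame(residual = r[-n], next_residual = r[-1]),
    qq = data.frame(theoretical = sort(qq$x), sample = sort(qq$y)),
    shapiro_p = if (n >= 3 && stats::sd(r) > 0)
      stats::shapiro.test(r)$p.value else NA_real_
  )
}
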