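# Out-of-sample validation of the final change-score model: repeated
# random train/test splits ("bootstrap" subsampling without replacement)
# and a null distribution from random metric subsets.

#' @keywords internal
#' @noRd
adj_r2_of <- function(obs, pred, n_pred) {
  n <- length(obs)
  ssr <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- 1 - ssr / sst
  1 - (1 - r2) * (n - 1) / (n - n_pred - 1)
}

#' Bootstrap split analysis
#'
#' For each split size (train, test), repeatedly partitions the patients
#' at random, refits the fixed retained-feature model on the training
#' part, and predicts the held-out patients. Per-patient prediction
#' means and standard deviations are pooled over all runs; an adjusted
#' R^2 of observed vs mean-predicted outcome summarizes each split size,
#' and the whole procedure is repeated `repeats` times to attach a
#' dispersion to that summary. Despite the traditional name, the
#' resampling is subsampling without replacement.
#'
#' @param dd A `delta_dataset`.
#' @param features Retained predictor names.
#' @param split_sizes List of `c(train, test)` integer pairs.
#' @param runs Random splits per repeat.
#' @param repeats Number of independent repetitions of the whole
#'   procedure.
#' @param seed Master seed.
#' @return Object of class `bootstrap_result`: per split size, the pooled
#'   per-patient prediction summary and the per-repeat adjusted R^2 and
#'   nRMSE (with means and sds).
#' @export
bootstrap_splits <- function(dd, features = colnames(dd$x),
                             split_sizes = list(c(20L, 3L), c(19L, 4L),
                                                c(18L, 5L)),
                             runs = 1000L, repeats = 10L, seed = 1L) {
  stopifnot(inherits(dd, "delta_dataset"))
  n <- length(dd$y)
  p <- length(features)
  X <- cbind(1, dd$x[, features, drop = FALSE])
  seeds <- spawn_seeds(seed, length(split_sizes) * repeats)
  si <- 0
  per_split <- list()
  for (ss in split_sizes) {
    n_train <- ss[1]; n_test <- ss[2]
    if (n_train + n_test != n) abort_netrecov(
      sprintf("split %d-%d does not partition the %d patients",
              n_train, n_test, n), "netrecov_validation_error")
    if (n_train <= p + 1) abort_netrecov(
      sprintf("train size %d too small for %d predictors", n_train, p),
      "netrecov_validation_error")
    pred_sum <- numeric(n); pred_sumsq <- numeric(n); pred_n <- integer(n)
    rep_adj_r2 <- numeric(repeats); rep_nrmse <- numeric(repeats)
    for (r in seq_len(repeats)) {
      si <- si + 1
      rep_sum <- numeric(n); rep_n <- integer(n)
      with_seed(seeds[si], {
        for (run in seq_len(runs)) {
          test <- sample.int(n, n_test)
          fit <- stats::lm.fit(X[-test, , drop = FALSE], dd$y[-test])
          pred <- as.vector(X[test, , drop = FALSE] %*% fit$coefficients)
          pred_sum[test] <- pred_sum[test] + pred
          pred_sumsq[test] <- pred_sumsq[test] + pred^2
          pred_n[test] <- pred_n[test] + 1L
          rep_sum[test] <- rep_sum[test] + pred
          rep_n[test] <- rep_n[test] + 1L
        }
      })
      seen <- rep_n > 0
      mean_pred_rep <- ifelse(seen, rep_sum / pmax(rep_n, 1L), NA_real_)
      rep_adj_r2[r] <- adj_r2_of(dd$y[seen], mean_pred_rep[seen], p)
      rng <- diff(range(dd$y[seen]))
      rep_nrmse[r] <- if (rng > 0)
        sqrt(mean((dd$y[seen] - mean_pred_rep[seen])^2)) / rng else 0
    }
    mean_pred <- ifelse(pred_n > 0, pred_sum / pmax(pred_n, 1L), NA_real_)
    var_pred <- ifelse(pred_n > 1,
                       (pred_sumsq - pred_sum^2 / pmax(pred_n, 1L)) /
                         pmax(pred_n - 1L, 1L), 0)
    per_split[[paste0(n_train, "-", n_test)]] <- list(
      train = n_train, test = n_test,
      patients = data.frame(patient_id = dd$patient_id, observed = dd$y,
                            mean_prediction = mean_pred,
                            sd_prediction = sqrt(pmax(var_pred, 0)),
                            n_predictions = pred_n,
                            stringsAsFactors = FALSE),
      adj_r2 = rep_adj_r2, nrmse = rep_nrmse,
      adj_r2_mean = mean(rep_adj_r2), adj_r2_sd = stats::sd(rep_adj_r2),
      nrmse_mean = mean(rep_nrmse), nrmse_sd = stats::sd(rep_nrmse)
    )
  }
  structure(list(splits = per_split, runs = runs, repeats = repeats,
                 features = features, seed = seed),
            class = "bootstrap_result")
}

#' Random metric-subset null distribution
#'
#' Each run draws `k` distinct features uniformly from the step-1
#' candidate pool, fits the change-score model without elimination, and
#' records the adjusted R^2 and nRMSE. Empirical p-values for the
#' observed model use the add-one correction
#' p = (1 + #\{null at least as good\}) / (runs + 1), so p is never zero.
#'
#' @param dd A `delta_dataset` whose columns cover the candidate pool.
#' @param pool Character vector of candidate feature names.
#' @param k Number of features drawn per run.
#' @param observed A fitted `delta_model` whose adjusted R^2 and nRMSE
#'   are located in the null distribution (optional).
#' @param runs Number of null draws.
#' @param seed Seed.
#' @param eliminate If `TRUE`, each null fit also runs backward
#'   elimination (sensitivity analysis; default `FALSE`).
#' @return Object of class `null_distribution` with vectors `adj_r2` and
#'   `nrmse` (length `runs`), the observed values, and empirical
#'   p-values.
#' @export
random_subset_null <- function(dd, pool = colnames(dd$x), k,
                               observed = NULL, runs = 1000L, seed = 1L,
                               eliminate = FALSE) {
  stopifnot(inherits(dd, "delta_dataset"))
  pool <- intersect(pool, colnames(dd$x))
  if (k > length(pool)) abort_netrecov(
    sprintf("k = %d exceeds the pool of %d features", k, length(pool)),
    "netrecov_validation_error")
  adj <- numeric(runs); nr <- numeric(runs)
  with_seed(seed, {
    for (i in seq_len(runs)) {
      feats <- sample(pool, k)
      m <- if (eliminate) backward_eliminate(dd, feats)
      else fit_delta_model(dd, feats)
      adj[i] <- m$adj_r2
      nr[i] <- m$nrmse
    }
  })
  obs_adj <- if (!is.null(observed)) observed$adj_r2 else NA_real_
  obs_nr <- if (!is.null(observed)) observed$nrmse else NA_real_
  structure(list(
    adj_r2 = adj, nrmse = nr,
    observed_adj_r2 = obs_adj, observed_nrmse = obs_nr,
    p_adj_r2 = if (!is.na(obs_adj)) (1 + sum(adj >= obs_adj)) / (runs + 1)
    else NA_real_,
    p_nrmse = if (!is.na(obs_nr)) (1 + sum(nr <= obs_nr)) / (runs + 1)
    else NA_real_,
    runs = runs, k = k, seed = seed
  ), class = "null_distribution")
}
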