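# End-to-end orchestration: data -> node metrics -> CFC -> feature
# selection -> change-score regression -> validation -> lesion overlap.
# One master seed spawns independent per-stage streams, so changing e.g.
# the bootstrap run count does not perturb the GA results.

#' Pipeline configuration
#'
#' Exactly one input source: a synthetic-cohort configuration, or a
#' dataset directory written by [write_dataset()].
#'
#' @param synthetic A [cohort_config()], or `NULL` when reading from disk.
#' @param input_dir Dataset directory, or `NULL` when simulating.
#' @param out_dir Output directory for stage artifacts and the report.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param cfc_tests,polarity Tests entering the PCA and their polarity
#'   map.
#' @param filter_alpha Univariate filter cut (uncorrected).
#' @param top_k Optional cap on the number of filtered candidates.
#' @param garf A [garf_control()].
#' @param regression_alpha Significance level of backward elimination.
#' @param split_sizes Bootstrap `c(train, test)` pairs; `NULL` derives
#'   them from the cohort size (n-3/3, n-4/4, n-5/5).
#' @param bootstrap_runs,bootstrap_repeats Bootstrap effort.
#' @param null_runs Random-subset null draws.
#' @param lesion_min_patients Prevalence threshold for the lesion map.
#' @param resume Reuse stage outputs already present in `out_dir`
#'   (currently the metric table and GARF stages).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(), input_dir = NULL,
                            out_dir = tempfile("netrecov_run_"),
                            seed = 1L,
                            cfc_tests = COG_TESTS,
                            polarity = DEFAULT_POLARITY,
                            filter_alpha = 0.05, top_k = NULL,
                            garf = garf_control(),
                            regression_alpha = 0.05,
                            split_sizes = NULL,
                            bootstrap_runs = 1000L, bootstrap_repeats = 10L,
                            null_runs = 1000L,
                            lesion_min_patients = 3L,
                            resume = FALSE) {
  if (is.null(synthetic) == is.null(input_dir)) {
    abort_netrecov("provide exactly one of `synthetic` or `input_dir`",
                   "netrecov_config_error")
  }
  structure(list(
    synthetic = synthetic, input_dir = input_dir, out_dir = out_dir,
    seed = as.integer(seed), cfc_tests = cfc_tests, polarity = polarity,
    filter_alpha = filter_alpha, top_k = top_k, garf = garf,
    regression_alpha = regression_alpha, split_sizes = split_sizes,
    bootstrap_runs = as.integer(bootstrap_runs),
    bootstrap_repeats = as.integer(bootstrap_repeats),
    null_runs = as.integer(null_runs),
    lesion_min_patients = as.integer(lesion_min_patients),
    resume = isTRUE(resume)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `synthetic` block mirrors [cohort_config()] and the `garf` block
#' [garf_control()].
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_load(sprintf("config file not found: %s", path),
                                     file = path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn <- do.call(cohort_config, raw$synthetic)
  }
  garf <- if (!is.null(raw$garf)) do.call(garf_control, raw$garf)
  else garf_control()
  args <- raw[setdiff(names(raw), c("synthetic", "garf"))]
  if (!is.null(args$split_sizes)) {
    args$split_sizes <- lapply(args$split_sizes, as.integer)
  }
  do.call(pipeline_config, c(list(synthetic = syn, garf = garf), args))
}

#' @keywords internal
#' @noRd
stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      stage = stage, class = c("netrecov_pipeline_error", "netrecov_error")))
  })
}

# Reconstruct metric tables from the tidy CSV written by the metrics stage.
#' @keywords internal
#' @noRd
tidy_to_metric_tables <- function(tidy) {
  keys <- unique(paste(tidy$subject, tidy$timepoint, sep = "_"))
  out <- list()
  for (key in keys) {
    sub <- tidy[paste(tidy$subject, tidy$timepoint, sep = "_") == key, ]
    ga <- sub$value[sub$metric == "global_assortativity"]
    sub <- sub[sub$metric != "global_assortativity", ]
    wide <- stats::reshape(sub[c("region", "metric", "value")],
                           idvar = "region", timevar = "metric",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[c("region", METRIC_NAMES)]
    wide <- wide[order(wide$region), ]
    rownames(wide) <- NULL
    attr(wide, "global_assortativity") <- ga
    out[[key]] <- wide
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (data, node metrics, CFC, univariate
#' filter, GARF selection, change-score regression with backward
#' elimination, bootstrap and random-subset validation, lesion overlap),
#' writing CSV/JSON artifacts per stage under `config$out_dir` and a
#' consolidated `report.json`. A stage failure aborts with the stage name
#' attached to the error condition.
#'
#' @param config A [pipeline_config()] or path to a YAML/JSON config.
#' @return Object of class `pipeline_report` (list of per-stage results
#'   plus provenance), invisibly written as JSON.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(config$seed, 6)

  # -- data ---------------------------------------------------------------
  dataset <- stage_guard("data", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- seeds[1]
      generate_cohort(cfg)
    } else {
      read_dataset(config$input_dir)
    }
  })

  # -- node metrics -------------------------------------------------------
  metrics_path <- file.path(out, "metrics.csv")
  tables <- stage_guard("metrics", {
    if (config$resume && file.exists(metrics_path)) {
      tidy_to_metric_tables(utils::read.csv(metrics_path,
                                            stringsAsFactors = FALSE))
    } else {
      tabs <- lapply(dataset$matrices, compute_metric_table)
      utils::write.csv(metric_tables_to_tidy(tabs), metrics_path,
                       row.names = FALSE)
      tabs
    }
  })

  # -- cognitive function component --------------------------------------
  cfc <- stage_guard("cfc", {
    res <- derive_cfc(dataset$scores, tests = config$cfc_tests,
                      polarity = config$polarity)
    utils::write.csv(res$scores, file.path(out, "cfc_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      lambdas = as.list(res$lambdas), loadings = as.list(res$loadings),
      explained_variance_ratio = res$explained_variance_ratio,
      orientation_sign = res$orientation_sign),
      file.path(out, "cfc.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  cfc_comparisons <- stage_guard("cfc", compare_cfc_groups(cfc))
  utils::write.csv(cfc_comparisons, file.path(out, "cfc_comparisons.csv"),
                   row.names = FALSE)

  # -- feature matrix and univariate filter -------------------------------
  patient_keys <- grep("_(early|late)$", names(tables), value = TRUE)
  fm <- stage_guard("features", {
    standardize_features(build_feature_matrix(tables[patient_keys]))
  })
  candidates <- stage_guard("filter", {
    cand <- univariate_rank(fm, alpha = config$filter_alpha,
                            top_k = config$top_k)
    utils::write.csv(cand, file.path(out, "candidates.csv"),
                     row.names = FALSE)
    cand
  })
  if (nrow(candidates) < 2) {
    abort_netrecov(sprintf(
      "only %d features survive the univariate filter; cannot run GARF",
      nrow(candidates)), "netrecov_pipeline_error")
  }

  # -- GARF selection -----------------------------------------------------
  selected_path <- file.path(out, "selected_features.json")
  selected <- stage_guard("select", {
    if (config$resume && file.exists(selected_path)) {
      raw <- jsonlite::read_json(selected_path, simplifyVector = TRUE)
      structure(list(
        features = as.data.frame(raw$features, stringsAsFactors = FALSE),
        cv_accuracy = raw$cv_accuracy, trace = raw$trace,
        mask = stats::setNames(as.integer(raw$mask), raw$candidates),
        candidates = raw$candidates, fold_mode = raw$fold_mode,
        seed = raw$seed), class = "selected_features")
    } else {
      sel <- garf_select(fm, candidates, control = config$garf,
                         seed = seeds[2])
      jsonlite::write_json(list(
        features = sel$features, cv_accuracy = sel$cv_accuracy,
        trace = sel$trace, mask = unname(sel$mask),
        candidates = sel$candidates, fold_mode = sel$fold_mode,
        seed = sel$seed), selected_path, auto_unbox = TRUE, digits = NA)
      utils::write.csv(sel$features, file.path(out, "selected_features.csv"),
                       row.names = FALSE)
      sel
    }
  })

  # -- change-score regression -------------------------------------------
  dd_all <- stage_guard("regression",
                        compute_deltas(fm, cfc, candidates$feature))
  model <- stage_guard("regression", {
    m <- backward_eliminate(dd_all, features = selected$features$feature,
                            alpha = config$regression_alpha)
    jsonlite::write_json(list(
      coefficients = as.list(m$coefficients),
      p_values = as.list(m$p_values),
      std_coefficients = as.list(m$std_coefficients),
      adj_r2 = m$adj_r2, nrmse = m$nrmse,
      f_statistic = m$f_statistic, f_p_value = m$f_p_value,
      vif = as.list(m$vif), features = m$features,
      significant = m$significant),
      file.path(out, "regression.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(m$trace, file.path(out, "elimination_trace.csv"),
                     row.names = FALSE)
    m
  })
  diagnostics <- stage_guard("regression", residual_diagnostics(model))

  # -- validation ---------------------------------------------------------
  n_pat <- length(dd_all$y)
  split_sizes <- config$split_sizes %||%
    lapply(3:5, function(t) c(n_pat - t, t))
  # keep only split sizes whose training part can fit the retained model
  split_sizes <- Filter(function(ss) ss[1] > length(model$features) + 1,
                        split_sizes)
  boot <- NULL
  nulld <- NULL
  if (length(model$features) >= 1 && length(split_sizes) > 0) {
    boot <- stage_guard("validate", {
      b <- bootstrap_splits(dd_all, model$features,
                            split_sizes = split_sizes,
                            runs = config$bootstrap_runs,
                            repeats = config$bootstrap_repeats,
                            seed = seeds[3])
      summ <- do.call(rbind, lapply(b$splits, function(s) data.frame(
        split = paste0(s$train, "-", s$test),
        adj_r2_mean = s$adj_r2_mean, adj_r2_sd = s$adj_r2_sd,
        nrmse_mean = s$nrmse_mean, nrmse_sd = s$nrmse_sd)))
      utils::write.csv(summ, file.path(out, "bootstrap_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(b$splits[[1]]$patients,
                       file.path(out, "bootstrap_predictions.csv"),
                       row.names = FALSE)
      b
    })
  }
  if (length(model$features) >= 1) {
    nulld <- stage_guard("validate", {
      nd <- random_subset_null(dd_all, pool = candidates$feature,
                               k = length(model$features),
                               observed = model, runs = config$null_runs,
                               seed = seeds[4])
      jsonlite::write_json(list(
        observed_adj_r2 = nd$observed_adj_r2,
        observed_nrmse = nd$observed_nrmse,
        p_adj_r2 = nd$p_adj_r2, p_nrmse = nd$p_nrmse,
        runs = nd$runs, k = nd$k),
        file.path(out, "null_distribution.json"),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(adj_r2 = nd$adj_r2, nrmse = nd$nrmse),
                       file.path(out, "null_distribution.csv"),
                       row.names = FALSE)
      nd
    })
  }

  # -- lesion overlap -----------------------------------------------------
  lesions <- NULL
  if (length(dataset$masks) > 0) {
    lesions <- stage_guard("lesions", {
      pmap <- build_probability_map(dataset$masks)
      thr <- threshold_map(pmap, config$lesion_min_patients)
      labels <- octant_labels(dim(pmap$counts))
      dice <- roi_dice_table(thr, labels)
      write_volume(pmap, file.path(out, "lesion_probability_map.nii.gz"))
      write_volume(thr, file.path(out, "lesion_map_thresholded.nii.gz"))
      utils::write.csv(dice, file.path(out, "lesion_roi_dice.csv"),
                       row.names = FALSE)
      list(map = pmap, thresholded = thr, dice = dice)
    })
  }

  # -- report -------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                               auto_unbox = TRUE, digits = NA, null = "null",
                               force = TRUE)
  cfg_path <- file.path(out, "pipeline_config.json")
  writeLines(cfg_json, cfg_path)
  # hash only the analysis-relevant configuration, not run locations
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  hashable$resume <- NULL
  hash_path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(rapply(hashable, unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), hash_path)
  provenance <- list(
    config_hash = unname(tools::md5sum(hash_path)),
    seed = config$seed, stage_seeds = seeds,
    fold_mode = config$garf$fold_mode,
    filter_alpha = config$filter_alpha,
    regression_alpha = config$regression_alpha,
    garf = unclass(config$garf),
    package_version = as.character(utils::packageVersion("netrecov")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  report <- structure(list(
    n_controls = sum(dataset$subjects$group == "control"),
    n_patients = sum(dataset$subjects$group == "patient"),
    n_regions = length(dataset$region_labels),
    cfc = list(explained_variance_ratio = cfc$explained_variance_ratio,
               loadings = cfc$loadings,
               comparisons = cfc_comparisons),
    n_candidates = nrow(candidates),
    selection = list(features = selected$features,
                     cv_accuracy = selected$cv_accuracy,
                     n_metrics = nrow(selected$features),
                     n_regions = length(setdiff(
                       unique(selected$features$region), "global"))),
    regression = list(features = model$features,
                      n_metrics = length(model$features),
                      n_regions = length(setdiff(unique(
                        vapply(strsplit(model$features, "|", fixed = TRUE),
                               `[`, "", 1)), "global")),
                      coefficients = model$coefficients,
                      std_coefficients = model$std_coefficients,
                      adj_r2 = model$adj_r2, nrmse = model$nrmse,
                      f_p_value = model$f_p_value, vif = model$vif,
                      significant = model$significant,
                      shapiro_p = diagnostics$shapiro_p),
    bootstrap = if (!is.null(boot)) lapply(boot$splits, function(s)
      list(split = paste0(s$train, "-", s$test),
           adj_r2_mean = s$adj_r2_mean, adj_r2_sd = s$adj_r2_sd,
           nrmse_mean = s$nrmse_mean, nrmse_sd = s$nrmse_sd)),
    null = if (!is.null(nulld)) list(p_adj_r2 = nulld$p_adj_r2,
                                     p_nrmse = nulld$p_nrmse,
                                     runs = nulld$runs, k = nulld$k),
    lesions = if (!is.null(lesions)) list(
      n_masks = lesions$map$n_masks,
      max_percent = max(lesions$map$percent),
      dice = lesions$dice),
    provenance = provenance
  ), class = "pipeline_report")
  jsonlite::write_json(rapply(unclass(report), unclass, how = "replace"),
                       file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(report)
}
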