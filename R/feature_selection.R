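# Two-step selection of phase-discriminative network metrics:
# an uncorrected univariate paired filter, then a genetic-algorithm
# random-forest (GARF) wrapper scored by k-fold cross-validated accuracy.

#' Assemble a wide feature table from node metric tables
#'
#' One row per subject-timepoint, one column per (region, metric) pair
#' (named `region|metric`) plus the graph-level `global|assortativity`.
#'
#' @param tables Named list of metric tables from [compute_metric_table()],
#'   keys of the form `subject_timepoint`.
#' @return Data frame with `subject`, `timepoint` and numeric feature
#'   columns.
#' @export
build_feature_matrix <- function(tables) {
  stopifnot(length(tables) > 0, !is.null(names(tables)))
  rows <- lapply(names(tables), function(key) {
    tab <- tables[[key]]
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    tp <- parts[length(parts)]
    subj <- paste(parts[-length(parts)], collapse = "_")
    vals <- unlist(lapply(METRIC_NAMES, function(m) {
      stats::setNames(tab[[m]], paste(tab$region, m, sep = "|"))
    }))
    vals <- c(vals, `global|assortativity` = attr(tab, "global_assortativity"))
    c(list(subject = subj, timepoint = tp), as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(df) <- NULL
  df
}

#' Standardize feature columns
#'
#' Per-column z-scoring over rows, with the centering/scaling parameters
#' recorded for reuse on new data. Constant columns are an error naming
#' the offending feature.
#'
#' @param df Data frame from [build_feature_matrix()] (columns `subject`
#'   and `timepoint` are carried through as row metadata).
#' @return Object of class `feature_matrix`: list with the standardized
#'   matrix `x`, `subject`, `timepoint`, `center` and `scale`.
#' @export
standardize_features <- function(df) {
  meta <- intersect(c("subject", "timepoint"), names(df))
  feat_cols <- setdiff(names(df), meta)
  X <- as.matrix(df[feat_cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    abort_netrecov(sprintf("constant feature column(s): %s",
                           paste(feat_cols[scl == 0], collapse = ", ")),
                   "netrecov_feature_error")
  }
  structure(list(
    x = scale(X, center = ctr, scale = scl),
    subject = df$subject %||% rep(NA_character_, nrow(X)),
    timepoint = df$timepoint %||% rep(NA_character_, nrow(X)),
    center = ctr, scale = scl
  ), class = "feature_matrix")
}

# Early/late rows of a feature matrix, aligned by patient.
#' @keywords internal
#' @noRd
paired_rows <- function(fm) {
  ie <- which(fm$timepoint == "early")
  il <- which(fm$timepoint == "late")
  if (!setequal(fm$subject[ie], fm$subject[il])) {
    abort_netrecov("early/late rows are not fully paired by patient",
                   "netrecov_feature_error")
  }
  il <- il[match(fm$subject[ie], fm$subject[il])]
  list(early = ie, late = il)
}

#' Univariate filter of phase-discriminative features
#'
#' Per feature, an early-vs-late paired comparison within patients:
#' paired t-test when Shapiro-Wilk accepts normality of the differences
#' (5% level), Wilcoxon signed-rank otherwise. Features with uncorrected
#' p below `alpha` are kept, sorted by ascending p. No multiplicity
#' correction is applied: the step screens candidates rather than drawing
#' inference.
#'
#' @param fm A `feature_matrix` containing early and late patient rows.
#' @param alpha Uncorrected significance cut.
#' @param top_k Optional cap: keep at most the `top_k` smallest-p
#'   survivors.
#' @return Data frame `feature`, `test`, `p_value`, filtered and sorted;
#'   the unfiltered ranking is attached as attribute `ranking`.
#' @export
univariate_rank <- function(fm, alpha = 0.05, top_k = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  pr <- paired_rows(fm)
  E <- fm$x[pr$early, , drop = FALSE]
  L <- fm$x[pr$late, , drop = FALSE]
  res <- lapply(colnames(fm$x), function(f) {
    ht <- gated_test(L[, f], E[, f], paired = TRUE)
    data.frame(feature = f, test = ht$test, p_value = ht$p_value,
               stringsAsFactors = FALSE)
  })
  rank_tab <- do.call(rbind, res)
  rank_tab <- rank_tab[order(rank_tab$p_value), ]
  rownames(rank_tab) <- NULL
  keep <- rank_tab[rank_tab$p_value < alpha, ]
  if (!is.null(top_k)) keep <- utils::head(keep, top_k)
  rownames(keep) <- NULL
  attr(keep, "ranking") <- rank_tab
  keep
}

#' Cross-validation fold assignment
#'
#' Partitions rows into `k` folds. In `grouped` mode (default) both rows
#' of a patient stay in the same fold, so no patient spans train and test;
#' in `paper` mode rows are treated as independent samples, stratified by
#' label.
#'
#' @param patient_ids Patient id per row.
#' @param labels Class label per row (early/late).
#' @param k Number of folds.
#' @param mode `"grouped"` or `"paper"`.
#' @param seed Seed making the assignment reproducible.
#' @return Integer fold index per row.
#' @export
make_cv_folds <- function(patient_ids, labels, k = 5L,
                          mode = c("grouped", "paper"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(patient_ids)
  stopifnot(length(labels) == n)
  with_seed(seed, {
    folds <- integer(n)
    if (mode == "grouped") {
      ids <- unique(patient_ids)
      if (k > length(ids)) abort_netrecov(
        sprintf("k = %d exceeds the %d patient groups", k, length(ids)),
        "netrecov_feature_error")
      assign_id <- stats::setNames(
        rep(seq_len(k), length.out = length(ids))[sample.int(length(ids))],
        ids)
      folds <- unname(assign_id[patient_ids])
    } else {
      if (k > n) abort_netrecov("k exceeds the number of rows",
                                "netrecov_feature_error")
      for (lab in unique(labels)) {
        idx <- which(labels == lab)
        folds[idx[sample.int(length(idx))]] <-
          rep(seq_len(k), length.out = length(idx))
      }
    }
    folds
  })
}

#' GARF hyperparameters
#'
#' @param pop_size GA population size.
#' @param generations Number of GA generations.
#' @param p_crossover Probability of uniform crossover per mating pair.
#' @param mutation_rate Per-bit mutation probability; `NULL` means 1/L
#'   for L candidate features.
#' @param elitism Number of best individuals copied unchanged.
#' @param num_trees Random-forest trees per fold.
#' @param k_folds Cross-validation folds.
#' @param fold_mode `"grouped"` (a patient's two rows share a fold) or
#'   `"paper"` (rows independent).
#' @return List of class `garf_control`.
#' @export
garf_control <- function(pop_size = 50L, generations = 40L,
                         p_crossover = 0.8, mutation_rate = NULL,
                         elitism = 2L, num_trees = 500L, k_folds = 5L,
                         fold_mode = c("grouped", "paper")) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 num_trees = as.integer(num_trees),
                 k_folds = as.integer(k_folds),
                 fold_mode = match.arg(fold_mode)),
            class = "garf_control")
}

# Mean k-fold CV accuracy of a random forest on the masked columns.
# Folds and per-fold forest seeds are fixed across masks, so a mask's
# fitness does not depend on evaluation order.
#' @keywords internal
#' @noRd
cv_accuracy <- function(x, y, folds, num_trees, seed) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                          num.trees = num_trees, seed = seed + f,
                          num.threads = 1)
    pred <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                           num.threads = 1)$predictions
    mean(pred == y[!tr])
  }, 0)
  mean(accs)
}

#' Genetic-algorithm random-forest feature selection
#'
#' Searches binary inclusion masks over the filtered candidate features
#' with a generational GA (tournament selection, uniform crossover,
#' per-bit mutation, elitism). The fitness of a mask is the mean k-fold
#' cross-validated accuracy of a random-forest classifier of early vs
#' late phase restricted to the masked columns; exact fitness ties are
#' broken in favour of fewer features. Fully seeded and deterministic.
#'
#' @param fm A `feature_matrix` with early/late patient rows.
#' @param candidates Data frame from [univariate_rank()] (or a character
#'   vector of feature names).
#' @param control A [garf_control()].
#' @param seed Integer seed for folds, forests and GA randomness.
#' @return Object of class `selected_features`: data frame `features`
#'   (region, metric, feature, univariate p), `cv_accuracy` of the best
#'   mask, the per-generation best-fitness `trace`, the best `mask`, the
#'   candidate list and the seed.
#' @export
garf_select <- function(fm, candidates, control = garf_control(),
                        seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  cand_names <- if (is.data.frame(candidates)) candidates$feature else candidates
  if (length(cand_names) < 2) abort_netrecov(
    "GARF needs at least 2 candidate features", "netrecov_feature_error")
  rows <- fm$timepoint %in% c("early", "late")
  x <- as.data.frame(fm$x[rows, cand_names, drop = FALSE],
                     check.names = FALSE)
  names(x) <- paste0("f", seq_along(cand_names))  # safe names for ranger
  y <- factor(fm$timepoint[rows], levels = c("early", "late"))
  if (nlevels(droplevels(y)) < 2) abort_netrecov(
    "labels are single-class", "netrecov_feature_error")
  L <- length(cand_names)
  mut <- control$mutation_rate %||% (1 / L)
  folds <- make_cv_folds(fm$subject[rows], as.character(y),
                         k = control$k_folds, mode = control$fold_mode,
                         seed = seed)

  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    if (sum(mask) == 0) return(0)
    key <- paste(which(mask == 1L), collapse = ",")
    hit <- get0(key, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    acc <- cv_accuracy(x[, mask == 1L, drop = FALSE], y, folds,
                       control$num_trees, seed)
    assign(key, acc, envir = cache)
    acc
  }
  # lexicographic comparison: accuracy first, fewer features on ties
  better <- function(acc_a, n_a, acc_b, n_b) {
    acc_a > acc_b || (acc_a == acc_b && n_a < n_b)
  }

  with_seed(seed + 1L, {
    pop <- matrix(stats::rbinom(L * control$pop_size, 1L, 0.5),
                  nrow = control$pop_size)
    pop[1, ] <- 1L  # seed the search with the full candidate set
    acc <- apply(pop, 1, fitness)
    nfeat <- rowSums(pop)
    ord <- order(-acc, nfeat)
    trace <- numeric(control$generations)
    for (gen in seq_len(control$generations)) {
      newpop <- matrix(0L, control$pop_size, L)
      # elitism
      n_el <- min(control$elitism, control$pop_size)
      newpop[seq_len(n_el), ] <- pop[ord[seq_len(n_el)], , drop = FALSE]
      i <- n_el
      while (i < control$pop_size) {
        # binary tournaments
        pick <- function() {
          c2 <- sample.int(control$pop_size, 2)
          if (better(acc[c2[1]], nfeat[c2[1]], acc[c2[2]], nfeat[c2[2]]))
            c2[1] else c2[2]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < control$p_crossover) {
          swap <- stats::runif(L) < 0.5
          tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
        }
        for (child in list(p1, p2)) {
          if (i < control$pop_size) {
            i <- i + 1
            flip <- stats::runif(L) < mut
            child[flip] <- 1L - child[flip]
            newpop[i, ] <- child
          }
        }
      }
      pop <- newpop
      acc <- apply(pop, 1, fitness)
      nfeat <- rowSums(pop)
      ord <- order(-acc, nfeat)
      trace[gen] <- acc[ord[1]]
    }
    best <- pop[ord[1], ]
    best_acc <- acc[ord[1]]

    sel_names <- cand_names[best == 1L]
    pvals <- if (is.data.frame(candidates)) {
      candidates$p_value[match(sel_names, candidates$feature)]
    } else rep(NA_real_, length(sel_names))
    o <- order(pvals)
    sel_names <- sel_names[o]; pvals <- pvals[o]
    parts <- strsplit(sel_names, "|", fixed = TRUE)
    features <- data.frame(
      region = vapply(parts, `[`, "", 1),
      metric = vapply(parts, `[`, "", 2),
      feature = sel_names, p_value = pvals, stringsAsFactors = FALSE)

    structure(list(
      features = features, cv_accuracy = best_acc, trace = trace,
      mask = stats::setNames(best, cand_names), candidates = cand_names,
      fold_mode = control$fold_mode, seed = seed
    ), class = "selected_features")
  })
}
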