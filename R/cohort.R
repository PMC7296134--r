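# Synthetic TBI cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# cross-sectional control group scanned once and a patient group scanned in
# an early (days post-injury) and a late (one year) phase, with
#   * per-subject FA-weighted 90-region connectivity matrices drawn from a
#     modular weighted random graph,
#   * an injury model that multiplicatively attenuates edges incident to a
#     configurable set of affected ("frontal") regions at the early phase,
#     with per-patient recovery interpolating back toward the pre-injury
#     network,
#   * a latent cognitive ability driving a six-test neuropsychological
#     battery (one test exponentiated to plant skewness, timed tests with
#     lower-is-better polarity), where late-phase ability rises with the
#     patient's latent recovery factor,
#   * spherical lesion masks in a designated frontal octant of a small
#     voxel grid for ~80% of patients.

COG_TESTS <- c("soip", "pasat", "cwit_reading", "cwit_naming",
               "cwit_inhibition", "list_learning")

# Timed CWIT trials are completion times: lower is better. The polarity
# map is applied (scores multiplied by it) before any composite analysis.
DEFAULT_POLARITY <- c(soip = 1, pasat = 1, cwit_reading = -1,
                      cwit_naming = -1, cwit_inhibition = -1,
                      list_learning = 1)

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the analysis expects: 28 controls
#' scanned once, 23 patients scanned at an early and a late phase, 90
#' atlas regions.
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_regions Number of atlas regions (network nodes).
#' @param affected_regions Indices of regions whose incident edges are
#'   attenuated by the injury; defaults to ten regions inside the first
#'   ("frontal") module.
#' @param early_attenuation Multiplicative factor in (0, 1] applied to
#'   affected incident edges at the early phase (1 = no injury).
#' @param recovery_gain Slope linking the per-patient latent recovery
#'   factor to the late-phase gain in cognitive ability (0 = no
#'   cognition-network coupling).
#' @param noise_sd Standard deviation of the per-test score noise, on the
#'   scale of unit factor loadings.
#' @param edge_noise_sd Measurement noise added to existing edge weights
#'   per session.
#' @param skewed_test_index Which test column is exponentiated so its raw
#'   scores are right-skewed (z-skewness > 1.96 by construction at
#'   defaults).
#' @param lesion_grid Integer vector of 3 voxel-grid dimensions.
#' @param lesion_prob Fraction of patients with a visible lesion mask.
#' @param n_modules Modules of the base random graph.
#' @param density Target edge density of the base graph.
#' @param seed Master seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 28L, n_patients = 23L,
                          n_regions = 90L,
                          affected_regions = NULL,
                          early_attenuation = 0.7,
                          recovery_gain = 1.5,
                          noise_sd = 0.5,
                          edge_noise_sd = 0.02,
                          skewed_test_index = 6L,
                          lesion_grid = c(45L, 54L, 45L),
                          lesion_prob = 19 / 23,
                          n_modules = 6L,
                          density = 0.3,
                          seed = 42L) {
  if (n_controls < 1 || n_patients < 1) {
    abort_netrecov("group sizes must be positive", "netrecov_config_error")
  }
  if (n_regions < 3) {
    abort_netrecov("need at least 3 regions", "netrecov_config_error")
  }
  if (is.null(affected_regions)) {
    affected_regions <- seq_len(min(10L, max(1L, n_regions %/% 9L)))
  }
  if (any(affected_regions < 1) || any(affected_regions > n_regions)) {
    abort_netrecov("affected region index out of range", "netrecov_config_error")
  }
  if (early_attenuation <= 0 || early_attenuation > 1) {
    abort_netrecov("early_attenuation must lie in (0, 1]", "netrecov_config_error")
  }
  if (length(lesion_grid) != 3 || any(lesion_grid < 4)) {
    abort_netrecov("lesion_grid must be 3 dimensions of at least 4 voxels",
                   "netrecov_config_error")
  }
  structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_regions = as.integer(n_regions),
    affected_regions = as.integer(affected_regions),
    early_attenuation = early_attenuation, recovery_gain = recovery_gain,
    noise_sd = noise_sd, edge_noise_sd = edge_noise_sd,
    skewed_test_index = as.integer(skewed_test_index),
    lesion_grid = as.integer(lesion_grid), lesion_prob = lesion_prob,
    n_modules = as.integer(n_modules), density = density,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Beta shape parameters from mean/sd, clipped to a valid range.
#' @keywords internal
#' @noRd
beta_shapes <- function(mean, sd) {
  v <- sd^2
  v <- min(v, mean * (1 - mean) * 0.95)
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Modular weighted random graph: n regions split into contiguous modules,
# dense strong within-module edges, sparser weaker between-module edges,
# plus a ring backbone that guarantees connectedness. Weights are
# Beta-distributed FA-like values clipped to (0, 1].
#' @keywords internal
#' @noRd
make_base_network <- function(n_regions, n_modules, density) {
  module <- sort(rep(seq_len(n_modules), length.out = n_regions))
  ut <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  same <- module[ut[, 1]] == module[ut[, 2]]
  n_within <- sum(same); n_between <- sum(!same)
  p_within <- 0.8
  target <- density * nrow(ut)
  p_between <- max(0.02, min(0.95, (target - p_within * n_within) / n_between))

  W <- matrix(0, n_regions, n_regions)
  present <- ifelse(same, stats::runif(nrow(ut)) < p_within,
                    stats::runif(nrow(ut)) < p_between)
  shw <- beta_shapes(0.45, 0.10)
  shb <- beta_shapes(0.30, 0.10)
  w <- ifelse(same, stats::rbeta(nrow(ut), shw[1], shw[2]),
              stats::rbeta(nrow(ut), shb[1], shb[2]))
  w <- pmin(pmax(w, 1e-6), 1)
  vals <- ifelse(present, w, 0)
  W[ut] <- vals
  W <- W + t(W)
  # ring backbone keeps the graph connected under any edge draw
  for (i in seq_len(n_regions)) {
    j <- if (i == n_regions) 1L else i + 1L
    if (W[i, j] == 0) {
      wij <- min(max(stats::rbeta(1, shb[1], shb[2]), 1e-6), 1)
      W[i, j] <- wij; W[j, i] <- wij
    }
  }
  W
}

# Session-level measurement noise on existing edges, preserving symmetry,
# the zero diagonal and the (0, 1] range.
#' @keywords internal
#' @noRd
observe_matrix <- function(W, sd) {
  if (sd <= 0) return(W)
  n <- nrow(W)
  E <- matrix(0, n, n)
  ut <- upper.tri(W)
  E[ut] <- stats::rnorm(sum(ut), 0, sd)
  E <- E + t(E)
  out <- ifelse(W > 0, pmin(pmax(W + E, 1e-6), 1), 0)
  diag(out) <- 0
  out
}

#' @keywords internal
#' @noRd
attenuate_regions <- function(W, regions, factor) {
  A <- W
  A[regions, ] <- A[regions, ] * factor
  A[, regions] <- t(A[regions, , drop = FALSE])
  A
}

#' @keywords internal
#' @noRd
sphere_mask <- function(grid, center, radius) {
  ax <- (seq_len(grid[1]) - center[1])^2
  ay <- (seq_len(grid[2]) - center[2])^2
  az <- (seq_len(grid[3]) - center[3])^2
  arr <- outer(outer(ax, ay, "+"), az, "+")
  array(as.integer(arr <= radius^2), dim = grid)
}

#' Generate a synthetic TBI cohort
#'
#' Deterministic under the configuration seed. Patients' early matrices
#' carry attenuated weights on edges incident to the affected regions;
#' late matrices interpolate toward the subject's pre-injury base network
#' by a latent per-patient recovery factor; cognitive test scores are
#' linear in a latent ability whose late-phase gain is
#' `recovery_gain * recovery_factor`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `tbi_cohort`: list with elements `subjects`
#'   (metadata data.frame including the latent `recovery_factor`),
#'   `scores` (per subject-timepoint test battery), `matrices` (named list
#'   `subject_timepoint` of connectivity matrices), `masks` (named list of
#'   3-D binary arrays for lesioned patients), `region_labels`, `polarity`
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    nC <- config$n_controls; nP <- config$n_patients
    n <- config$n_regions
    region_labels <- sprintf("R%03d", seq_len(n))
    ids <- c(sprintf("C%02d", seq_len(nC)), sprintf("P%02d", seq_len(nP)))
    group <- rep(c("control", "patient"), c(nC, nP))

    # clinical covariates, loosely matched between groups
    age <- pmin(pmax(round(stats::rnorm(nC + nP, 38, 13)), 18), 70)
    sex <- sample(c("M", "F"), nC + nP, replace = TRUE, prob = c(0.75, 0.25))
    nart <- pmin(pmax(round(stats::rnorm(nC + nP, 107, 10)), 80), 130)
    education <- pmin(pmax(round(stats::rnorm(nC + nP, 11, 2.5)), 8), 20)

    # severity from a latent; the top ~22% are moderate, matching a
    # 18-mild / 5-moderate split at default sizes. Severity labels do not
    # alter network generation.
    sev_latent <- stats::rnorm(nP)
    n_mod <- max(1L, round(nP * 5 / 23))
    moderate <- rank(-sev_latent, ties.method = "first") <= n_mod
    severity <- c(rep("none", nC), ifelse(moderate, "moderate", "mild"))
    gcs <- c(rep(NA_integer_, nC),
             ifelse(moderate, sample(9:12, nP, replace = TRUE),
                    sample(13:15, nP, replace = TRUE)))
    recovery_factor <- c(rep(NA_real_, nC), stats::runif(nP, 0.1, 1))

    subjects <- data.frame(
      subject_id = ids, group = group, severity = severity, gcs = gcs,
      age = age, sex = sex, nart = nart, education = education,
      recovery_factor = recovery_factor, stringsAsFactors = FALSE)

    # connectivity matrices
    matrices <- list()
    for (i in seq_len(nC)) {
      B <- make_base_network(n, config$n_modules, config$density)
      M <- observe_matrix(B, config$edge_noise_sd)
      dimnames(M) <- list(region_labels, region_labels)
      matrices[[paste0(ids[i], "_control")]] <- M
    }
    for (j in seq_len(nP)) {
      id <- ids[nC + j]
      B <- make_base_network(n, config$n_modules, config$density)
      inj <- attenuate_regions(B, config$affected_regions,
                               config$early_attenuation)
      r <- recovery_factor[nC + j]
      late_clean <- inj + r * (B - inj)
      early <- observe_matrix(inj, config$edge_noise_sd)
      late <- observe_matrix(late_clean, config$edge_noise_sd)
      dimnames(early) <- list(region_labels, region_labels)
      dimnames(late) <- list(region_labels, region_labels)
      matrices[[paste0(id, "_early")]] <- early
      matrices[[paste0(id, "_late")]] <- late
    }

    # cognitive scores: one latent ability per subject-timepoint
    ability_c <- stats::rnorm(nC, 0, 0.7)
    pre <- stats::rnorm(nP, 0, 0.7)
    deficit <- pmax(stats::rnorm(nP, 1.5, 0.3), 0.3)
    ability_early <- pre - deficit
    ability_late <- ability_early + config$recovery_gain *
      recovery_factor[(nC + 1):(nC + nP)]

    loadings <- c(0.8, 1.0, 0.9, 0.9, 0.7, 0.6)
    mus <- c(50, 40, 45, 50, 60, 50)
    scales <- c(8, 9, 7, 7, 8, 6)
    make_scores <- function(id, tp, ability) {
      raw <- mus + scales * (DEFAULT_POLARITY * loadings * ability +
                               stats::rnorm(length(COG_TESTS), 0, config$noise_sd))
      k <- config$skewed_test_index
      # right-skew one test with a monotone increasing transform
      raw[k] <- exp((raw[k] - mus[k]) / (2 * scales[k]) * 1.6) * 20
      out <- as.list(raw)
      names(out) <- COG_TESTS
      c(list(subject_id = id, timepoint = tp), out)
    }
    rows <- c(
      lapply(seq_len(nC), function(i) make_scores(ids[i], "control", ability_c[i])),
      lapply(seq_len(nP), function(j) make_scores(ids[nC + j], "early", ability_early[j])),
      lapply(seq_len(nP), function(j) make_scores(ids[nC + j], "late", ability_late[j]))
    )
    scores <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))

    # lesion masks: spheres in the "frontal" octant (low x, high y, mid z)
    grid <- config$lesion_grid
    lesioned <- which(stats::runif(nP) < config$lesion_prob)
    masks <- list()
    for (j in lesioned) {
      center <- c(stats::runif(1, grid[1] * 0.1, grid[1] * 0.45),
                  stats::runif(1, grid[2] * 0.55, grid[2] * 0.9),
                  stats::runif(1, grid[3] * 0.35, grid[3] * 0.75))
      radius <- stats::runif(1, 2.5, 6)
      masks[[ids[nC + j]]] <- sphere_mask(grid, center, radius)
    }

    structure(list(
      subjects = subjects, scores = scores, matrices = matrices,
      masks = masks, region_labels = region_labels,
      polarity = DEFAULT_POLARITY, config = config
    ), class = "tbi_cohort")
  })
}

#' Write a cohort dataset to a directory tree
#'
#' Layout: `subjects.csv`, `scores.csv`, `config.json`,
#' `matrices/{subject}_{timepoint}.csv` (labeled CSV) and
#' `masks/{subject}.nii.gz` (binary NIfTI).
#'
#' @param dataset A `tbi_cohort`.
#' @param dir Destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tbi_cohort"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(dataset$matrices)) {
    write_connectivity_matrix(dataset$matrices[[key]],
                              file.path(dir, "matrices", paste0(key, ".csv")))
  }
  for (id in names(dataset$masks)) {
    RNifti::writeNifti(RNifti::asNifti(dataset$masks[[id]]),
                       file.path(dir, "masks", paste0(id, ".nii.gz")))
  }
  invisible(dir)
}

#' Read a cohort dataset from a directory tree
#'
#' Validates every matrix (symmetry, zero diagonal) and enforces a common
#' lesion-mask grid; violations raise a structured load error naming the
#' offending file.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `tbi_cohort`.
#' @export
read_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort_load(sprintf("missing dataset file: %s", p),
                                    file = p)
    p
  }
  subjects <- utils::read.csv(need("subjects.csv"), stringsAsFactors = FALSE)
  scores <- utils::read.csv(need("scores.csv"), stringsAsFactors = FALSE)
  cfg_raw <- jsonlite::read_json(need("config.json"), simplifyVector = TRUE)
  config <- cohort_config(
    n_controls = cfg_raw$n_controls, n_patients = cfg_raw$n_patients,
    n_regions = cfg_raw$n_regions, affected_regions = cfg_raw$affected_regions,
    early_attenuation = cfg_raw$early_attenuation,
    recovery_gain = cfg_raw$recovery_gain, noise_sd = cfg_raw$noise_sd,
    edge_noise_sd = cfg_raw$edge_noise_sd,
    skewed_test_index = cfg_raw$skewed_test_index,
    lesion_grid = cfg_raw$lesion_grid, lesion_prob = cfg_raw$lesion_prob,
    n_modules = cfg_raw$n_modules, density = cfg_raw$density,
    seed = cfg_raw$seed)

  mat_files <- list.files(file.path(dir, "matrices"), pattern = "\\.csv$",
                          full.names = TRUE)
  if (length(mat_files) == 0) abort_load(
    sprintf("no matrix files under %s", file.path(dir, "matrices")),
    file = file.path(dir, "matrices"))
  matrices <- lapply(mat_files, read_connectivity_matrix)
  names(matrices) <- sub("\\.csv$", "", basename(mat_files))

  mask_files <- list.files(file.path(dir, "masks"), pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE)
  masks <- list()
  grid <- NULL
  for (f in mask_files) {
    img <- RNifti::readNifti(f)
    arr <- array(as.integer(round(as.array(img))), dim = dim(img))
    if (!all(arr %in% c(0L, 1L))) abort_load(
      sprintf("lesion mask %s is not binary", f), file = f)
    if (is.null(grid)) grid <- dim(arr)
    if (!identical(dim(arr), grid)) abort_load(
      sprintf("lesion mask grid mismatch in %s: %s vs %s", f,
              paste(dim(arr), collapse = "x"), paste(grid, collapse = "x")),
      file = f)
    masks[[sub("\\.nii(\\.gz)?$", "", basename(f))]] <- arr
  }

  region_labels <- rownames(matrices[[1]]) %||%
    sprintf("R%03d", seq_len(config$n_regions))
  structure(list(
    subjects = subjects, scores = scores, matrices = matrices,
    masks = masks, region_labels = region_labels,
    polarity = DEFAULT_POLARITY, config = config
  ), class = "tbi_cohort")
}
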