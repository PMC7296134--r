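# Synthetic cohort generator: determinism, planted effects, round trips.

test_that("generation is deterministic under the seed and varies across seeds", {
  ds1 <- generate_cohort(small_cohort_config(seed = 11))
  ds2 <- generate_cohort(small_cohort_config(seed = 11))
  ds3 <- generate_cohort(small_cohort_config(seed = 12))
  expect_identical(ds1, ds2)
  expect_false(isTRUE(all.equal(ds1$matrices[[1]], ds3$matrices[[1]])))
})

test_that("cohort structure follows the study design", {
  ds <- generate_cohort(small_cohort_config())
  subj <- ds$subjects
  expect_equal(sum(subj$group == "control"), 6)
  expect_equal(sum(subj$group == "patient"), 6)
  # controls one timepoint, patients exactly early + late
  for (id in subj$subject_id[subj$group == "control"]) {
    expect_true(paste0(id, "_control") %in% names(ds$matrices))
    expect_false(paste0(id, "_early") %in% names(ds$matrices))
  }
  for (id in subj$subject_id[subj$group == "patient"]) {
    expect_true(all(paste0(id, c("_early", "_late")) %in% names(ds$matrices)))
  }
  # GCS present iff patient; recovery factor latent and patient-only
  expect_true(all(is.na(subj$gcs[subj$group == "control"])))
  expect_true(all(subj$gcs[subj$group == "patient"] %in% 3:15))
  expect_true(all(is.na(subj$recovery_factor[subj$group == "control"])))
  expect_true(all(subj$recovery_factor[subj$group == "patient"] >= 0 &
                    subj$recovery_factor[subj$group == "patient"] <= 1))
  # every matrix satisfies the connectivity invariants
  for (W in ds$matrices) expect_silent(validate_connectivity(W))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_controls = 0), "positive")
  expect_error(cohort_config(n_regions = 10, affected_regions = c(1, 11)),
               "out of range")
  expect_error(cohort_config(early_attenuation = 0), "early_attenuation")
  expect_error(cohort_config(early_attenuation = 1.2), "early_attenuation")
})

test_that("the designated test column is right-skewed at default-style settings", {
  ds <- generate_cohort(cohort_config(n_controls = 28, n_patients = 23,
                                      n_regions = 10,
                                      lesion_grid = c(8, 8, 8), seed = 3))
  expect_gt(z_skewness(ds$scores$list_learning), 1.96)
})

test_that("stronger attenuation strictly lowers early-phase affected-region strength", {
  mean_aff_strength <- function(att) {
    vals <- vapply(1:20, function(s) {
      cfg <- cohort_config(n_controls = 1, n_patients = 3, n_regions = 16,
                           affected_regions = 1:4, early_attenuation = att,
                           lesion_grid = c(8, 8, 8), seed = 100 + s)
      ds <- generate_cohort(cfg)
      early <- ds$matrices[grepl("_early$", names(ds$matrices))]
      mean(vapply(early, function(W) mean(node_strength(W)[1:4]), 0))
    }, 0)
    mean(vals)
  }
  m <- vapply(c(0.5, 0.7, 0.9, 1.0), mean_aff_strength, 0)
  expect_true(all(diff(m) > 0))
})

test_that("a null configuration leaves early/late metric distributions indistinguishable", {
  # early_attenuation = 1 and recovery_gain = 0: no planted network or
  # cognitive effect, so paired early-vs-late tests behave like the null.
  n_rep <- 60
  p_strength <- p_clust <- p_disas <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_controls = 1, n_patients = 8, n_regions = 16,
                         early_attenuation = 1, recovery_gain = 0,
                         lesion_grid = c(8, 8, 8), seed = 500 + s)
    ds <- generate_cohort(cfg)
    pats <- ds$subjects$subject_id[ds$subjects$group == "patient"]
    stat <- function(fn) {
      e <- vapply(pats, function(p) mean(fn(ds$matrices[[paste0(p, "_early")]])), 0)
      l <- vapply(pats, function(p) mean(fn(ds$matrices[[paste0(p, "_late")]])), 0)
      t.test(e, l, paired = TRUE)$p.value
    }
    p_strength[s] <- stat(node_strength)
    p_clust[s] <- stat(weighted_clustering)
    p_disas[s] <- stat(local_disassortativity)
  }
  expect_gte(mean(p_strength > 0.01), 0.95)
  expect_gte(mean(p_clust > 0.01), 0.95)
  expect_gte(mean(p_disas > 0.01), 0.95)
})

test_that("recovery factor drives the downstream change in CFC", {
  hits <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_controls = 10, n_patients = 10, n_regions = 8,
                         lesion_grid = c(8, 8, 8), seed = 900 + s)
    ds <- generate_cohort(cfg)
    cfc <- derive_cfc(ds$scores)
    sc <- cfc$scores
    pats <- ds$subjects[ds$subjects$group == "patient", ]
    d <- sc$cfc[sc$timepoint == "late"][match(pats$subject_id,
                                              sc$subject_id[sc$timepoint == "late"])] -
      sc$cfc[sc$timepoint == "early"][match(pats$subject_id,
                                            sc$subject_id[sc$timepoint == "early"])]
    cor(pats$recovery_factor, d) > 0
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- generate_cohort(small_cohort_config(seed = 77))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$subjects$subject_id, ds$subjects$subject_id)
  expect_equal(sort(names(ds2$matrices)), sort(names(ds$matrices)))
  for (key in names(ds$matrices)) {
    expect_equal(unname(ds2$matrices[[key]]), unname(ds$matrices[[key]]),
                 tolerance = 1e-12)
  }
  expect_equal(sort(names(ds2$masks)), sort(names(ds$masks)))
  for (id in names(ds$masks)) {
    expect_identical(ds2$masks[[id]], ds$masks[[id]])
  }
  expect_equal(ds2$scores$soip, ds$scores$soip, tolerance = 1e-12)
  expect_equal(ds2$config$seed, ds$config$seed)
})

test_that("malformed on-disk datasets raise structured load errors", {
  ds <- generate_cohort(small_cohort_config(seed = 78))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # asymmetric matrix file
  key <- names(ds$matrices)[1]
  W <- ds$matrices[[key]]
  W[1, 2] <- W[1, 2] + 0.5
  df <- as.data.frame(W); names(df) <- rownames(W)
  utils::write.table(df, file.path(dir, "matrices", paste0(key, ".csv")),
                     sep = ",", row.names = FALSE, quote = FALSE)
  err <- tryCatch(read_dataset(dir), error = identity)
  expect_s3_class(err, "netrecov_load_error")
  expect_match(conditionMessage(err), "symmetric")

  # mask grid mismatch between subjects
  dir2 <- withr::local_tempdir()
  write_dataset(ds, dir2)
  id <- names(ds$masks)[1]
  RNifti::writeNifti(RNifti::asNifti(array(0L, dim = c(5, 5, 5))),
                     file.path(dir2, "masks", paste0(id, ".nii.gz")))
  err2 <- tryCatch(read_dataset(dir2), error = identity)
  expect_s3_class(err2, "netrecov_load_error")
  expect_match(conditionMessage(err2), "grid mismatch")

  # missing scores file
  dir3 <- withr::local_tempdir()
  write_dataset(ds, dir3)
  unlink(file.path(dir3, "scores.csv"))
  err3 <- tryCatch(read_dataset(dir3), error = identity)
  expect_s3_class(err3, "netrecov_load_error")
  expect_match(conditionMessage(err3), "scores.csv")
})
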