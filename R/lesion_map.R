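# Lesion probability maps from binary masks, prevalence thresholding,
# and Sorensen-Dice overlap against atlas region labels.

#' @keywords internal
#' @noRd
check_binary_volume <- function(v, name = "volume") {
  if (!all(v %in% c(0, 1))) abort_netrecov(
    sprintf("%s is not binary", name), "netrecov_lesion_error")
  invisible(v)
}

#' Build a lesion probability map
#'
#' Voxelwise percentage of contributing subjects whose binary mask covers
#' the voxel: 100 * count / n_masks. The denominator is the number of
#' subjects with a mask, not the whole cohort (patients without a visible
#' lesion contribute no mask).
#'
#' @param masks Named list of binary 3-D arrays on a common grid.
#' @return Object of class `lesion_prob_map`: list with `percent` (values
#'   in \[0, 100\]), integer `counts`, and `n_masks`.
#' @export
build_probability_map <- function(masks) {
  if (length(masks) == 0) abort_netrecov("no lesion masks supplied",
                                         "netrecov_lesion_error")
  grid <- dim(masks[[1]])
  counts <- array(0L, dim = grid)
  for (id in names(masks) %||% as.character(seq_along(masks))) {
    m <- masks[[id]]
    if (!identical(dim(m), grid)) abort_netrecov(
      sprintf("lesion mask grid mismatch for subject %s: %s vs %s", id,
              paste(dim(m), collapse = "x"), paste(grid, collapse = "x")),
      "netrecov_lesion_error")
    check_binary_volume(m, sprintf("mask of subject %s", id))
    counts <- counts + m
  }
  structure(list(percent = 100 * counts / length(masks),
                 counts = counts, n_masks = length(masks)),
            class = "lesion_prob_map")
}

#' Threshold a probability map by patient prevalence
#'
#' Keeps only voxels lesioned in at least `min_patients` subjects,
#' removing sporadic lesions.
#'
#' @param map A `lesion_prob_map`.
#' @param min_patients Minimum subject count per voxel (default 3).
#' @return Binary 3-D array.
#' @export
threshold_map <- function(map, min_patients = 3L) {
  stopifnot(inherits(map, "lesion_prob_map"))
  if (min_patients < 1) abort_netrecov("min_patients must be at least 1",
                                       "netrecov_lesion_error")
  array(as.integer(map$counts >= min_patients), dim = dim(map$counts))
}

#' Sorensen-Dice overlap of two binary volumes
#'
#' 2|A intersect B| / (|A| + |B|). Two empty volumes give 0 with a
#' warning.
#'
#' @param a,b Binary volumes on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort_netrecov(
    "volumes are on different grids", "netrecov_lesion_error")
  check_binary_volume(a, "first volume"); check_binary_volume(b, "second volume")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both volumes are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a * b) / (na + nb)
}

#' Dice overlap per atlas region
#'
#' Computes the Dice coefficient between a binary lesion volume and each
#' labeled region of an integer atlas volume.
#'
#' @param volume Binary volume (e.g. a thresholded probability map).
#' @param labels Integer-labeled volume on the same grid (0 = background).
#' @param roi_ids Label ids to evaluate; default all non-zero labels
#'   present. Unknown ids are an error.
#' @return Data frame `roi`, `dice`, `roi_voxels`, `overlap_voxels`.
#' @export
roi_dice_table <- function(volume, labels, roi_ids = NULL) {
  if (!identical(dim(volume), dim(labels))) abort_netrecov(
    "label volume is on a different grid", "netrecov_lesion_error")
  check_binary_volume(volume, "lesion volume")
  present <- sort(setdiff(unique(as.vector(labels)), 0))
  if (is.null(roi_ids)) roi_ids <- present
  unknown <- setdiff(roi_ids, present)
  if (length(unknown) > 0) abort_netrecov(
    sprintf("unknown ROI label id(s): %s", paste(unknown, collapse = ", ")),
    "netrecov_lesion_error")
  nv <- sum(volume)
  rows <- lapply(roi_ids, function(id) {
    roi <- labels == id
    ov <- sum(volume[roi])
    data.frame(roi = id,
               dice = if (nv + sum(roi) == 0) 0 else 2 * ov / (nv + sum(roi)),
               roi_voxels = sum(roi), overlap_voxels = ov)
  })
  do.call(rbind, rows)
}

#' Read binary lesion masks from NIfTI files
#'
#' @param paths Named character vector (or list) of file paths; names
#'   become subject ids (default: file stem).
#' @return Named list of binary 3-D integer arrays.
#' @export
read_lesion_masks <- function(paths) {
  paths <- unlist(paths)
  nm <- names(paths) %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  out <- lapply(paths, function(f) {
    if (!file.exists(f)) abort_load(sprintf("mask file not found: %s", f),
                                    file = f)
    img <- RNifti::readNifti(f)
    arr <- array(as.integer(round(as.array(img))), dim = dim(img))
    if (!all(arr %in% c(0L, 1L))) abort_load(
      sprintf("lesion mask %s is not binary", f), file = f)
    arr
  })
  names(out) <- nm
  out
}

#' Write a probability map (or any volume) to NIfTI
#'
#' @param volume Numeric or integer 3-D array, or a `lesion_prob_map`
#'   (its percent volume is written).
#' @param path Destination `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "lesion_prob_map")) volume <- volume$percent
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Synthetic octant atlas labels
#'
#' Partitions a voxel grid into its eight octants, labeled 1-8. A small
#' synthetic stand-in for an anatomical parcellation, used to exercise
#' ROI overlap computations in tests and the synthetic pipeline.
#'
#' @param grid Integer vector of 3 grid dimensions.
#' @return Integer-labeled 3-D array.
#' @export
octant_labels <- function(grid) {
  hx <- (seq_len(grid[1]) > grid[1] / 2)
  hy <- (seq_len(grid[2]) > grid[2] / 2)
  hz <- (seq_len(grid[3]) > grid[3] / 2)
  lab <- outer(outer(as.integer(hx), 2L * as.integer(hy), "+"),
               4L * as.integer(hz), "+") + 1L
  array(as.integer(lab), dim = grid)
}
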