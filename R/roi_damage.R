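#' Probabilistic atlas ROI
#'
#' A 3D volume of inclusion probabilities (0-100) for one named visual area,
#' as provided by histology-based probabilistic atlases. A value of 50 means
#' the voxel belonged to the area in half of the reference brains. Values on
#' a 0-1 scale are auto-detected (no value exceeds 1) and rescaled to
#' percent with a warning.
#'
#' @param prob 3D numeric array of probabilities.
#' @param grid a [template_grid()].
#' @param name ROI label, e.g. `"V1"`, `"V4"`, `"hMT+/V5"`, `"occipital"`.
#' @return An object of class `probabilistic_roi`.
#' @export
probabilistic_roi <- function(prob, grid, name) {
  if (!inherits(grid, "template_grid")) stop("`grid` must be a template_grid")
  if (!is.array(prob) || length(dim(prob)) != 3L)
    stop("`prob` must be a 3D array")
  if (!identical(as.integer(dim(prob)), grid$shape))
    stop("`prob` dimensions do not match the grid shape")
  if (anyNA(prob)) stop("ROI contains NA values")
  if (any(prob < 0)) stop("ROI probabilities must be non-negative")
  if (max(prob) <= 1 && any(prob > 0)) {
    warning("ROI '", name, "' has values in [0,1]; rescaling to percent")
    prob <- prob * 100
  }
  if (any(prob > 100)) stop("ROI probabilities must be <= 100")
  structure(list(name = as.character(name), grid = grid, prob = prob),
            class = "probabilistic_roi")
}

#' @export
print.probabilistic_roi <- function(x, ...) {
  cat(sprintf("<probabilistic_roi> %s: %d voxels with p > 0 (max %.0f%%)\n",
              x$name, sum(x$prob > 0), max(x$prob)))
  invisible(x)
}

#' Threshold a probabilistic ROI into a binary mask
#'
#' A voxel is kept iff its atlas probability is greater than or equal to the
#' threshold, so masks at increasing thresholds are nested. Conventional
#' thresholds are 10% for hMT+/V5, 30% for V4 and 50% for V1, reflecting the
#' inter-individual variability of each area.
#'
#' @param roi a [probabilistic_roi()].
#' @param threshold_percent threshold in (0, 100].
#' @return A [mask_volume()].
#' @export
threshold_atlas <- function(roi, threshold_percent) {
  stopifnot(inherits(roi, "probabilistic_roi"))
  if (threshold_percent <= 0 || threshold_percent > 100)
    stop("`threshold_percent` must be in (0, 100]")
  mask_volume(array(as.integer(roi$prob >= threshold_percent),
                    dim = dim(roi$prob)), roi$grid)
}

#' Proportion of an ROI overlapped by a lesion
#'
#' Computes |ROI intersect lesion| / |ROI| on the common grid. The fraction
#' is undefined for an empty ROI and an error is raised.
#'
#' @param roi_mask binary ROI [mask_volume()] (non-empty).
#' @param lesion binary lesion [mask_volume()] on the same grid.
#' @return Damage fraction in [0, 1].
#' @export
damage_fraction <- function(roi_mask, lesion) {
  stopifnot(inherits(roi_mask, "mask_volume"), inherits(lesion, "mask_volume"))
  stop_if_grid_mismatch(roi_mask$grid, lesion$grid, "ROI and lesion")
  n_roi <- mask_voxel_count(roi_mask)
  if (n_roi == 0L) stop("ROI mask is empty: damage fraction is undefined")
  sum(roi_mask$data & lesion$data) / n_roi
}

#' Tabulate ROI damage across a cohort
#'
#' For every subject, ROI and threshold, thresholds the atlas ROI and
#' records the number of ROI voxels, the number overlapped by the subject's
#' consensus lesion, and the damage fraction. Rows are ordered by subject,
#' then ROI (input order), then threshold.
#'
#' @param subjects list of `subject_record` objects (see
#'   [subject_record()]); each subject's `lesion` is used.
#' @param rois list of [probabilistic_roi()] objects.
#' @param thresholds named list/vector mapping ROI name to one or more
#'   threshold percentages; unnamed single numeric applies to all ROIs.
#' @param use_flipped if `TRUE` (default), left-sided lesions are mirrored to
#'   the right hemisphere first, so right-hemisphere ROIs serve the whole
#'   cohort.
#' @return A `data.frame` with columns `subject_id`, `roi`, `threshold`,
#'   `roi_voxels`, `overlap_voxels`, `fraction`.
#' @export
damage_table <- function(subjects, rois, thresholds, use_flipped = TRUE) {
  stopifnot(is.list(subjects), is.list(rois))
  roi_names <- vapply(rois, function(r) r$name, "")
  thr_for <- function(nm) {
    if (!is.null(names(thresholds)) && nm %in% names(thresholds))
      as.numeric(thresholds[[nm]])
    else if (is.null(names(thresholds)))
      as.numeric(unlist(thresholds))
    else stop("no threshold given for ROI '", nm, "'")
  }
  # pre-threshold each (roi, threshold) once
  roi_masks <- list()
  for (i in seq_along(rois))
    for (t in thr_for(roi_names[i]))
      roi_masks[[paste(roi_names[i], t, sep = "@")]] <-
        threshold_atlas(rois[[i]], t)
  rows <- vector("list", 0L)
  for (s in subjects) {
    lesion <- s$lesion
    if (use_flipped && identical(s$side, "left"))
      lesion <- flip_hemisphere(lesion)
    for (i in seq_along(rois)) {
      for (t in thr_for(roi_names[i])) {
        rm <- roi_masks[[paste(roi_names[i], t, sep = "@")]]
        nv <- mask_voxel_count(rm)
        ov <- sum(rm$data & lesion$data)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, roi = roi_names[i], threshold = t,
          roi_voxels = nv, overlap_voxels = ov,
          fraction = if (nv > 0L) ov / nv else
            stop("ROI '", roi_names[i], "' empty at threshold ", t),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a damage table as TSV
#' @param tab data.frame from [damage_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_damage_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
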