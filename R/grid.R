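#' Template grid describing the common analysis space
#'
#' All volumes handled by the pipeline live on a single voxel grid: lesion
#' masks are assumed to have been resampled into a shared template space
#' upstream (registration itself is out of scope). Two volumes may only be
#' combined when their grids are identical; every combining operation checks
#' this and fails loudly on a mismatch.
#'
#' The first voxel axis is, by convention, the left-right axis: hemisphere
#' flipping mirrors indices along it. The `orientation_tag` labels the common
#' space so that volumes from different templates cannot be mixed silently.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param orientation_tag character label identifying the common space.
#' @return An object of class `template_grid`.
#' @examples
#' template_grid(c(32, 38, 32), c(2, 2, 2))
#' @export
template_grid <- function(shape, voxel_size_mm = c(1, 1, 1),
                          orientation_tag = "template-v1") {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || anyNA(voxel_size_mm) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         orientation_tag = as.character(orientation_tag)[1L]),
    class = "template_grid"
  )
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("<template_grid> %s: %s voxels @ %s mm\n", x$orientation_tag,
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

grids_identical <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    identical(a$orientation_tag, b$orientation_tag)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_identical(a, b))
    stop(sprintf("grid mismatch: %s are not on the same template grid", what))
  invisible(TRUE)
}

#' Binary lesion/ROI mask on a template grid
#'
#' A `mask_volume` holds a 3D array of 0/1 values: each lesioned voxel scores
#' 1 and each spared voxel scores 0. Any non-binary input is rejected; use
#' [read_mask()] to binarize continuous volumes on load.
#'
#' @param data 3D array (or logical array) of 0/1 values whose dimensions
#'   match `grid$shape`.
#' @param grid a [template_grid()].
#' @return An object of class `mask_volume` with elements `grid` and `data`
#'   (an integer 3D array of 0/1).
#' @seealso [mask_voxel_count()], [mask_volume_mm3()]
#' @export
mask_volume <- function(data, grid) {
  if (!inherits(grid, "template_grid")) stop("`grid` must be a template_grid")
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("`data` dimensions do not match the grid shape")
  if (anyNA(data)) stop("mask contains NA voxels")
  v <- as.vector(data)
  if (!all(v == 0 | v == 1)) stop("mask values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(grid = grid, data = data), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels lesioned of %s (%.1f mm3)\n",
              mask_voxel_count(x), prod(x$grid$shape), mask_volume_mm3(x)))
  invisible(x)
}

#' Number of lesioned voxels in a mask
#' @param mask a [mask_volume()].
#' @return Integer count of voxels equal to 1.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data)
}

#' Lesion volume in cubic millimetres
#'
#' Voxel count multiplied by the volume of one voxel, as used when reporting
#' the volume of thresholded overlap maps or significant clusters.
#'
#' @param mask a [mask_volume()].
#' @return Volume in mm^3.
#' @examples
#' g <- template_grid(c(10, 10, 10), c(2, 2, 2))
#' m <- mask_volume(array(0L, c(10, 10, 10)), g)
#' mask_volume_mm3(m) # 0
#' @export
mask_volume_mm3 <- function(mask) {
  mask_voxel_count(mask) * prod(mask$grid$voxel_size_mm)
}

#' Set of independent rater delineations for one subject
#'
#' Three or four researchers independently identify the lesion on the same
#' scan; their binary masks are combined into a consensus mask by
#' [consensus_mask()]. All masks must share one template grid.
#'
#' @param masks list of 3 or 4 [mask_volume()] objects on one grid.
#' @param subject_id subject label.
#' @param rater_ids optional character labels, one per mask.
#' @return An object of class `rater_set`.
#' @export
rater_set <- function(masks, subject_id = "subject", rater_ids = NULL) {
  if (!is.list(masks) || !all(vapply(masks, inherits, TRUE, "mask_volume")))
    stop("`masks` must be a list of mask_volume objects")
  n <- length(masks)
  if (n < 3L || n > 4L)
    stop("a rater_set requires 3 or 4 rater masks, got ", n)
  for (i in seq_len(n)[-1L])
    stop_if_grid_mismatch(masks[[1L]]$grid, masks[[i]]$grid, "rater masks")
  if (is.null(rater_ids)) rater_ids <- paste0("rater", seq_len(n))
  if (length(rater_ids) != n) stop("`rater_ids` must match number of masks")
  structure(list(subject_id = as.character(subject_id), masks = masks,
                 rater_ids = as.character(rater_ids)),
            class = "rater_set")
}

#' Voxelwise lesion-overlap count map for a cohort
#'
#' Sums the binarized lesion masks of a cohort voxel by voxel; counts range
#' from 0 to the number of subjects.
#'
#' @param masks list of [mask_volume()] objects on one grid (>= 1).
#' @return An object of class `overlap_map` with elements `grid`, `counts`
#'   (integer 3D array), and `n_subjects`.
#' @examples
#' g <- template_grid(c(4, 4, 4))
#' m <- mask_volume(array(rep(0:1, 32), c(4, 4, 4)), g)
#' overlap_map(list(m, m))$n_subjects
#' @export
overlap_map <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L ||
      !all(vapply(masks, inherits, TRUE, "mask_volume")))
    stop("`masks` must be a non-empty list of mask_volume objects")
  grid <- masks[[1L]]$grid
  for (m in masks[-1L]) stop_if_grid_mismatch(grid, m$grid, "cohort masks")
  counts <- array(0L, dim = grid$shape)
  for (m in masks) counts <- counts + m$data
  structure(list(grid = grid, counts = counts, n_subjects = length(masks)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> n=%d subjects, max overlap %d\n",
              x$n_subjects, max(x$counts)))
  invisible(x)
}
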