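#' Consensus lesion mask from independent rater delineations
#'
#' The rater masks are summed voxelwise and thresholded at 1.9, so that with
#' binary raters a voxel survives exactly when at least two raters marked it.
#' The same rule applies with 3 or 4 raters.
#'
#' @param raters a [rater_set()].
#' @param threshold numeric, strict lower bound on the rater sum
#'   (default 1.9).
#' @return A [mask_volume()] on the raters' grid.
#' @examples
#' g <- template_grid(c(4, 4, 4))
#' m1 <- mask_volume(array(1L, c(4, 4, 4)), g)
#' m0 <- mask_volume(array(0L, c(4, 4, 4)), g)
#' # marked by only 1 of 3 raters: dropped
#' mask_voxel_count(consensus_mask(rater_set(list(m1, m0, m0))))
#' @export
consensus_mask <- function(raters, threshold = 1.9) {
  stopifnot(inherits(raters, "rater_set"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  s <- array(0L, dim = raters$masks[[1L]]$grid$shape)
  for (m in raters$masks) s <- s + m$data
  mask_volume(array(as.integer(s > threshold), dim = dim(s)),
              raters$masks[[1L]]$grid)
}

#' Mirror a mask across the mid-sagittal plane
#'
#' Reverses the first voxel axis (the left-right axis by package convention),
#' mapping x-index i to Nx + 1 - i, as done when left-hemisphere lesions are
#' flipped so that the whole cohort's lesions sit in one hemisphere. Requires
#' a grid symmetric about the mid-sagittal plane; the operation is an
#' involution and preserves the voxel count.
#'
#' @param mask a [mask_volume()].
#' @return The mirrored [mask_volume()].
#' @export
flip_hemisphere <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  nx <- mask$grid$shape[1L]
  mask_volume(mask$data[nx:1L, , , drop = FALSE], mask$grid)
}
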