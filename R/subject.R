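#' Per-participant record: lesion, side, behavior
#'
#' Bundles one participant's consensus lesion mask, lesion laterality and
#' behavioral trial blocks. The lesion side drives hemisphere normalization
#' in VLSM (left-sided lesions are flipped to the right; bilateral cases are
#' excluded).
#'
#' @param subject_id label.
#' @param lesion consensus [mask_volume()].
#' @param side `"left"`, `"right"` or `"bilateral"`; inferred from the mask
#'   with [infer_side()] when `NULL`.
#' @param behavior optional `data.frame` of trial blocks (columns `task`,
#'   `condition`, `n_trials`, `n_correct`).
#' @param raters optional [rater_set()] the consensus was derived from.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, lesion, side = NULL, behavior = NULL,
                           raters = NULL) {
  stopifnot(inherits(lesion, "mask_volume"))
  if (is.null(side)) side <- infer_side(lesion)
  side <- match.arg(side, c("left", "right", "bilateral"))
  if (!is.null(behavior)) stopifnot(is.data.frame(behavior))
  structure(list(subject_id = as.character(subject_id), lesion = lesion,
                 side = side, behavior = behavior, raters = raters),
            class = "subject_record")
}

#' Infer lesion laterality from mask geometry
#'
#' The first voxel axis is the left-right axis; indices at or below Nx/2 are
#' the left hemisphere. A mask with lesioned voxels in both halves is
#' `"bilateral"`.
#'
#' @param mask a [mask_volume()].
#' @return `"left"`, `"right"` or `"bilateral"`.
#' @export
infer_side <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  nx <- mask$grid$shape[1L]
  half <- nx %/% 2L
  xs <- which(apply(mask$data, 1L, sum) > 0L)
  if (length(xs) == 0L) stop("empty lesion mask: side undefined")
  left <- any(xs <= half)
  right <- any(xs > half)
  if (left && right) "bilateral" else if (left) "left" else "right"
}
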