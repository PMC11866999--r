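#' Read a binary mask from a NIfTI-1 file
#'
#' Loads a 3D volume, binarizes it at > 0.5 (so masks surviving trilinear
#' interpolation remain binary), and populates the template grid from the
#' header. 4D volumes and volumes containing NaN are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @param orientation_tag space label to attach to the grid; volumes read
#'   with different tags will refuse to combine.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, orientation_tag = "template-v1") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  vals <- as.vector(img)
  if (anyNA(vals) || any(is.nan(vals)))
    stop("volume contains NaN/NA voxels: ", path)
  grid <- template_grid(d, RNifti::pixdim(img)[seq_len(3L)], orientation_tag)
  mask_volume(array(as.integer(vals > 0.5), dim = d), grid)
}

#' Write a binary mask as NIfTI-1
#'
#' Masks are written as unsigned 8-bit integers; `read_mask(write_mask(m))`
#' recovers `m` exactly.
#'
#' @param mask a [mask_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- mask$grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a probabilistic ROI volume from NIfTI
#'
#' Probabilistic atlas values may arrive on a 0-1 or 0-100 scale; volumes
#' whose values never exceed 1 are rescaled to percent with a warning.
#'
#' @inheritParams read_mask
#' @param name ROI label (e.g. `"V1"`).
#' @return A [probabilistic_roi()].
#' @export
read_roi <- function(path, name, orientation_tag = "template-v1") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  grid <- template_grid(d, RNifti::pixdim(img)[seq_len(3L)], orientation_tag)
  probabilistic_roi(array(as.numeric(img), dim = d), grid, name)
}

#' Write an overlap map as integer NIfTI plus a TSV histogram
#'
#' The histogram lists, for each overlap count >= 1, how many voxels attain
#' it (columns `count`, `n_voxels`).
#'
#' @param overlap an [overlap_map()].
#' @param path output NIfTI path; the histogram is written alongside with
#'   extension `.hist.tsv`.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(overlap, path) {
  stopifnot(inherits(overlap, "overlap_map"))
  img <- RNifti::asNifti(overlap$counts)
  RNifti::pixdim(img) <- overlap$grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  tab <- table(factor(overlap$counts[overlap$counts > 0L],
                      levels = seq_len(max(1L, max(overlap$counts)))))
  hist_path <- sub("\\.nii(\\.gz)?$", "", path)
  utils::write.table(
    data.frame(count = as.integer(names(tab)), n_voxels = as.integer(tab)),
    paste0(hist_path, ".hist.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a real-valued statistic map as NIfTI
#'
#' Used for the VLSM t-statistic, p-value and q-value maps.
#'
#' @param values 3D numeric array.
#' @param grid a [template_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(values, grid, path) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
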