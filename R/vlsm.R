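#' Voxels analyzable in VLSM: lesioned in enough subjects
#'
#' Thresholds the cohort overlap map so that only voxels damaged in at least
#' `min_subjects` participants enter the mass-univariate analysis; voxels
#' lesioned in fewer subjects carry too little information for a per-voxel
#' regression.
#'
#' @param overlap an [overlap_map()].
#' @param min_subjects minimum number of lesioned subjects per voxel
#'   (default 3).
#' @return A [mask_volume()] of included voxels.
#' @export
build_inclusion_mask <- function(overlap, min_subjects = 3L) {
  stopifnot(inherits(overlap, "overlap_map"))
  min_subjects <- as.integer(min_subjects)
  if (min_subjects < 1L) stop("`min_subjects` must be >= 1")
  mask_volume(array(as.integer(overlap$counts >= min_subjects),
                    dim = dim(overlap$counts)), overlap$grid)
}

#' Subjects-by-voxels lesion matrix over an inclusion mask
#'
#' Row s, column v is the binary lesion status of subject s at included
#' voxel v. Each subject's total lesion voxel count over the *full* grid is
#' retained for dTLVC weighting.
#'
#' @param masks list of hemisphere-normalized [mask_volume()] lesions.
#' @param inclusion [mask_volume()] of analyzed voxels.
#' @param subject_ids optional labels for the rows.
#' @return An object of class `lesion_matrix` with `values` (numeric matrix
#'   subjects x included voxels), `voxel_index` (linear indices of the
#'   included voxels), `total_voxels` (per-subject full-grid lesion size),
#'   `grid`, `inclusion`, `subject_ids`, and `weighted` (FALSE).
#' @export
lesion_matrix <- function(masks, inclusion, subject_ids = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            inherits(inclusion, "mask_volume"))
  for (m in masks) stop_if_grid_mismatch(m$grid, inclusion$grid, "lesions")
  idx <- which(inclusion$data == 1L)
  values <- matrix(0, nrow = length(masks), ncol = length(idx))
  for (s in seq_along(masks)) values[s, ] <- masks[[s]]$data[idx]
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_along(masks))
  structure(list(values = values, voxel_index = idx,
                 total_voxels = vapply(masks, mask_voxel_count, 0L),
                 grid = inclusion$grid, inclusion = inclusion,
                 subject_ids = as.character(subject_ids), weighted = FALSE),
            class = "lesion_matrix")
}

#' Direct total lesion volume control (dTLVC) weighting
#'
#' Divides each subject's binary lesion vector by the square root of that
#' subject's total lesion voxel count (over the full grid, not just the
#' included voxels), so every subject's full-grid lesion vector has unit
#' Euclidean norm. This stops overall stroke severity (lesion size) from
#' driving the voxelwise statistic.
#'
#' @param matrix a [lesion_matrix()] with binary values.
#' @return The matrix with values in `{0, 1/sqrt(V_s)}` and
#'   `weighted = TRUE`.
#' @export
dtlvc_weights <- function(matrix) {
  stopifnot(inherits(matrix, "lesion_matrix"))
  if (isTRUE(matrix$weighted)) stop("lesion matrix is already weighted")
  if (any(matrix$total_voxels < 1L))
    stop("subject(s) with empty lesion: dTLVC weight undefined for ",
         paste(matrix$subject_ids[matrix$total_voxels < 1L], collapse = ", "))
  matrix$values <- matrix$values / sqrt(matrix$total_voxels)
  matrix$weighted <- TRUE
  matrix
}

#' Centre a behavioral vector on zero
#'
#' @param behavior numeric vector (length >= 2).
#' @return The vector minus its mean; sums to zero.
#' @export
demean <- function(behavior) {
  behavior <- as.numeric(behavior)
  if (length(behavior) < 2L) stop("need at least 2 values to demean")
  if (anyNA(behavior)) stop("behavior contains NA")
  behavior - mean(behavior)
}

#' Mass-univariate regression of behavior on voxel damage
#'
#' At every included voxel, fits an ordinary least-squares simple regression
#' of the (demeaned) behavioral score on the weighted damage score and
#' returns the slope t-statistic (n - 2 df) and its p-value. The default
#' alternative is one-sided: damage predicts *worse* performance (negative
#' slope, lower tail). Voxels whose predictor has zero variance (e.g. all
#' subjects lesioned) are flagged degenerate and assigned p = 1.
#'
#' @param matrix a [lesion_matrix()] (normally dTLVC-weighted).
#' @param behavior demeaned behavioral vector aligned with the matrix rows.
#' @param alternative `"less"` (default, damage lowers the score) or
#'   `"two.sided"`.
#' @return List with `stat` (t per voxel), `p` (per voxel), `df`, and
#'   `degenerate` (logical per voxel).
#' @export
voxelwise_regression <- function(matrix, behavior,
                                 alternative = c("less", "two.sided")) {
  stopifnot(inherits(matrix, "lesion_matrix"))
  alternative <- match.arg(alternative)
  X <- matrix$values
  n <- nrow(X)
  if (length(behavior) != n)
    stop("behavior length (", length(behavior),
         ") does not match number of subjects (", n, ")")
  if (n < 3L) stop("voxelwise regression needs at least 3 subjects")
  y <- as.numeric(behavior)
  ybar <- mean(y)
  yc <- y - ybar
  syy <- sum(yc^2)
  xbar <- colMeans(X)
  sxx <- colSums(X^2) - n * xbar^2
  sxy <- colSums(X * yc)          # == colSums((X - xbar) * yc)
  # zero-variance predictors: relative tolerance against the scale of X
  tol <- max(colSums(X^2), 1) * 1e-12
  degenerate <- sxx <= tol
  df <- n - 2L
  slope <- ifelse(degenerate, NA_real_, sxy / sxx)
  sse <- pmax(syy - ifelse(degenerate, 0, sxy^2 / sxx), 0)
  se <- sqrt(sse / df / ifelse(degenerate, NA_real_, sxx))
  tval <- slope / se
  zero_se <- !degenerate & !is.na(se) & se == 0
  # zero residual SE: perfect fit (t = +/-Inf) or flat perfect fit (t = 0)
  tval[zero_se] <- sign(slope[zero_se]) * Inf
  tval[zero_se & slope == 0] <- 0
  p <- if (alternative == "less") stats::pt(tval, df)
       else 2 * stats::pt(-abs(tval), df)
  stat <- tval
  stat[degenerate] <- NA_real_
  p[degenerate] <- 1
  list(stat = stat, p = p, df = df, degenerate = degenerate)
}

#' Benjamini-Hochberg FDR correction over included voxels
#'
#' Step-up procedure at level `q`: sort the m p-values ascending, find the
#' largest i with p(i) <= (i/m) q, and declare significant every voxel with
#' p at or below that p(i). The adjusted (q-)values are the standard step-up
#' minima, computed with `stats::p.adjust(method = "BH")`; a voxel is
#' significant exactly when its q-value is <= q.
#'
#' @param p numeric vector of p-values over the included voxels.
#' @param q FDR level (default 0.05).
#' @return List with `q_values`, `significant` (logical), and
#'   `threshold_p` (the largest retained p, or `NA` if none).
#' @export
fdr_correct <- function(p, q = 0.05) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("need at least one p-value")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] with no NA")
  qv <- stats::p.adjust(p, method = "BH")
  sig <- qv <= q
  list(q_values = qv, significant = sig,
       threshold_p = if (any(sig)) max(p[sig]) else NA_real_)
}

# positive half of the 26- (or 6-) neighbourhood offsets
connectivity_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else if (connectivity == 26L) {
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
    # keep one of each +/- pair
    keep <- offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
      (offs$dx == 0 & offs$dy == 0 & offs$dz > 0)
    lapply(which(keep), function(i)
      c(offs$dx[i], offs$dy[i], offs$dz[i]))
  } else stop("connectivity must be 6 or 26")
}

#' Connected clusters of a binary mask
#'
#' Labels connected components under 26-connectivity (faces, edges and
#' corners; 6-connectivity available) and reports them sorted by size,
#' largest first. When a statistic map is supplied the peak voxel is the one
#' with the most extreme (lowest, for the one-sided damage test) statistic
#' in the cluster; otherwise the first voxel in array order.
#'
#' @param mask binary [mask_volume()].
#' @param stat_map optional 3D array of voxel statistics for peak detection.
#' @param connectivity 26 (default) or 6.
#' @return A `data.frame` with columns `cluster_id`, `voxel_count`,
#'   `volume_mm3`, `peak_i`, `peak_j`, `peak_k`, plus an attribute
#'   `"labels"` holding the full 3D label array.
#' @export
extract_clusters <- function(mask, stat_map = NULL, connectivity = 26L) {
  stopifnot(inherits(mask, "mask_volume"))
  dims <- mask$grid$shape
  idx <- which(mask$data == 1L)
  empty <- data.frame(cluster_id = integer(0), voxel_count = integer(0),
                      volume_mm3 = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0))
  if (length(idx) == 0L) {
    attr(empty, "labels") <- array(0L, dim = dims)
    return(empty)
  }
  # vertex id per in-mask voxel
  vid <- array(0L, dim = dims)
  vid[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in connectivity_offsets(as.integer(connectivity))) {
    a <- lapply(1:3, function(ax) {
      r <- seq_len(dims[ax])
      if (off[ax] > 0) r[seq_len(dims[ax] - off[ax])]
      else if (off[ax] < 0) r[(1 - off[ax]):dims[ax]] else r
    })
    b <- lapply(1:3, function(ax) a[[ax]] + off[ax])
    va <- vid[a[[1]], a[[2]], a[[3]], drop = FALSE]
    vb <- vid[b[[1]], b[[2]], b[[3]], drop = FALSE]
    both <- va > 0L & vb > 0L
    if (any(both)) edges <- c(edges, rbind(va[both], vb[both]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  vox_mm3 <- prod(mask$grid$voxel_size_mm)
  coords <- arrayInd(idx, dims)
  labels <- array(0L, dim = dims)
  rows <- vector("list", comp$no)
  for (r in seq_along(ord)) {
    members <- which(comp$membership == ord[r])
    labels[idx[members]] <- r
    peak <- if (!is.null(stat_map)) {
      members[which.min(stat_map[idx[members]])]
    } else members[1L]
    rows[[r]] <- data.frame(cluster_id = r,
                            voxel_count = length(members),
                            volume_mm3 = length(members) * vox_mm3,
                            peak_i = coords[peak, 1L],
                            peak_j = coords[peak, 2L],
                            peak_k = coords[peak, 3L])
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}

#' Run the full voxel-based lesion-symptom mapping analysis
#'
#' End-to-end VLSM for one task: bilateral subjects are excluded; left-sided
#' lesions are flipped to the right hemisphere; an overlap map is built and
#' thresholded at `min_subjects`; binary lesion values are dTLVC-weighted;
#' each subject's floor-adjusted percent correct is demeaned; a per-voxel
#' OLS regression tests whether damage predicts worse performance; p-values
#' are Benjamini-Hochberg corrected at level `q`; surviving voxels are
#' grouped into connected clusters.
#'
#' @param subjects list of [subject_record()] objects, each with behavior
#'   for `task` (or pass `scores`).
#' @param task task label used to score behavior (default `"contrast"`).
#' @param q FDR level (default 0.05).
#' @param min_subjects minimum lesioned subjects per analyzed voxel
#'   (default 3).
#' @param scores optional named numeric vector of percent-correct scores
#'   (names = subject ids), overriding behavioral scoring.
#' @param alternative sidedness of the voxel test; `"less"` by default.
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @param flip_left flip left-sided lesions to the right hemisphere
#'   (default `TRUE`).
#' @return An object of class `vlsm_result`: `stat_map`, `p_map`, `q_map`
#'   (3D arrays, `NA` outside the inclusion mask), `significant_mask` and
#'   `inclusion_mask` ([mask_volume()]), `overlap` ([overlap_map()]),
#'   `clusters` (data.frame), `n_subjects`, `excluded` (ids of bilateral
#'   subjects), `behavior` (the demeaned scores used), `degenerate_voxels`
#'   (count), `params`.
#' @export
run_vlsm <- function(subjects, task = "contrast", q = 0.05,
                     min_subjects = 3L, scores = NULL,
                     alternative = c("less", "two.sided"),
                     connectivity = 26L, flip_left = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(is.list(subjects), length(subjects) >= 1L,
            all(vapply(subjects, inherits, TRUE, "subject_record")))
  ids <- vapply(subjects, function(s) s$subject_id, "")
  sides <- vapply(subjects, function(s) s$side, "")
  excluded <- ids[sides == "bilateral"]
  keep <- subjects[sides != "bilateral"]
  if (length(keep) < 3L)
    stop("fewer than 3 usable (unilateral) subjects after exclusions")
  # behavioral scores (percent_adjusted)
  beh <- vapply(keep, function(s) {
    if (!is.null(scores)) {
      if (!s$subject_id %in% names(scores))
        stop("no score supplied for subject ", s$subject_id)
      return(as.numeric(scores[[s$subject_id]]))
    }
    if (is.null(s$behavior)) stop("subject ", s$subject_id,
                                  " has no behavior and no score")
    blocks <- s$behavior[s$behavior$task == task, , drop = FALSE]
    if (nrow(blocks) == 0L)
      stop("subject ", s$subject_id, " has no '", task, "' blocks")
    score_task(blocks, task)$percent_adjusted
  }, 0)
  masks <- lapply(keep, function(s) {
    if (flip_left && s$side == "left") flip_hemisphere(s$lesion) else s$lesion
  })
  ov <- overlap_map(masks)
  inclusion <- build_inclusion_mask(ov, min_subjects)
  if (mask_voxel_count(inclusion) == 0L)
    stop("no voxel is lesioned in at least ", min_subjects, " subjects")
  lm_ <- dtlvc_weights(lesion_matrix(masks, inclusion,
                                     vapply(keep, function(s) s$subject_id,
                                            "")))
  y <- demean(beh)
  reg <- voxelwise_regression(lm_, y, alternative)
  fdr <- fdr_correct(reg$p, q)
  dims <- inclusion$grid$shape
  to_map <- function(v, fill = NA_real_) {
    m <- array(fill, dim = dims)
    m[lm_$voxel_index] <- v
    m
  }
  sig <- array(0L, dim = dims)
  sig[lm_$voxel_index[fdr$significant]] <- 1L
  significant_mask <- mask_volume(sig, inclusion$grid)
  stat_map <- to_map(reg$stat)
  clusters <- extract_clusters(significant_mask, stat_map, connectivity)
  structure(list(
    stat_map = stat_map, p_map = to_map(reg$p), q_map = to_map(fdr$q_values),
    significant_mask = significant_mask, inclusion_mask = inclusion,
    overlap = ov, clusters = clusters, n_subjects = length(keep),
    excluded = excluded,
    behavior = stats::setNames(y, lm_$subject_ids),
    degenerate_voxels = sum(reg$degenerate),
    params = list(task = task, q = q, min_subjects = min_subjects,
                  alternative = alternative, connectivity = connectivity,
                  flip_left = flip_left)),
    class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<vlsm_result> task=%s, n=%d subjects (%d excluded bilateral)\n",
    "  included voxels: %d (%.1f cm3); significant: %d in %d cluster(s)\n"),
    x$params$task, x$n_subjects, length(x$excluded),
    mask_voxel_count(x$inclusion_mask),
    mask_volume_mm3(x$inclusion_mask) / 1000,
    mask_voxel_count(x$significant_mask), nrow(x$clusters)))
  invisible(x)
}

#' Write VLSM result maps and cluster table to a directory
#'
#' Writes `stat.nii.gz`, `p.nii.gz`, `q.nii.gz`, `significant.nii.gz`,
#' `inclusion.nii.gz`, `overlap.nii.gz` (+ histogram), `clusters.tsv` and a
#' YAML `manifest.yaml` of parameters and exclusions.
#'
#' @param result a `vlsm_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_vlsm_result <- function(result, dir) {
  stopifnot(inherits(result, "vlsm_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- result$inclusion_mask$grid
  fill0 <- function(m) { m[is.na(m)] <- 0; m }
  write_stat_map(fill0(result$stat_map), g, file.path(dir, "stat.nii.gz"))
  write_stat_map(fill0(result$p_map), g, file.path(dir, "p.nii.gz"))
  write_stat_map(fill0(result$q_map), g, file.path(dir, "q.nii.gz"))
  write_mask(result$significant_mask, file.path(dir, "significant.nii.gz"))
  write_mask(result$inclusion_mask, file.path(dir, "inclusion.nii.gz"))
  write_overlap(result$overlap, file.path(dir, "overlap.nii.gz"))
  cl <- result$clusters
  attr(cl, "labels") <- NULL
  utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    task = result$params$task, q = result$params$q,
    min_subjects = result$params$min_subjects,
    alternative = result$params$alternative,
    connectivity = result$params$connectivity,
    flip_left = result$params$flip_left,
    n_subjects = result$n_subjects,
    excluded_bilateral = as.list(result$excluded),
    included_voxels = mask_voxel_count(result$inclusion_mask),
    included_volume_mm3 = mask_volume_mm3(result$inclusion_mask),
    significant_voxels = mask_voxel_count(result$significant_mask),
    degenerate_voxels = result$degenerate_voxels),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
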