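#' Configuration for a synthetic hemianopia cohort
#'
#' Describes the study conditions emulated by the generator: ~39 subjects
#' with unilateral posterior lesions of widely varying size (about 1-63% of
#' one synthetic occipital lobe), slightly more left- than right-sided
#' (p_left = 21/39), four noisy rater delineations per lesion, and 2AFC
#' detection behavior driven by damage to a compact critical region in the
#' right posterior white matter (emulating the optic radiation) plus
#' binomial trial noise.
#'
#' The deficit model is: latent detection probability
#' `p* = clamp(baseline - effect_beta * damage_fraction + sigma * z, 50, 100) / 100`
#' with `z ~ N(0,1)` per subject and task, and per-condition correct counts
#' drawn as `Binomial(n_trials, p*)`. At full critical-region damage and the
#' defaults (baseline 95, effect 45) performance falls to chance (50%).
#'
#' @param grid_shape voxels per axis (default 32 x 38 x 32).
#' @param voxel_size_mm voxel size (default 2 mm isotropic).
#' @param n_subjects cohort size (default 39).
#' @param p_left probability a lesion is left-sided (default 21/39).
#' @param lesion_size_range voxel-count range, sampled log-uniformly
#'   (default 100-6000, i.e. ~1-62% of the ~9700-voxel posterior
#'   hemisphere box standing in for an occipital lobe).
#' @param critical_center,critical_radii voxel center and radii of the
#'   critical ellipsoid on the right hemisphere.
#' @param effect_beta percent correct lost at full critical-region damage
#'   (default 45).
#' @param baseline_percent intact-performance baseline (default 95).
#' @param subject_sigma SD of the Gaussian subject effect in percent
#'   (default 3).
#' @param n_trials trials per condition (default 10).
#' @param n_raters raters per lesion, 3 or 4 (default 4).
#' @param rater_dilate_p,rater_erode_p probability a rater's delineation is
#'   a one-voxel dilation / erosion of the truth (default 0.3 each).
#' @param rater_flip_p probability each boundary-shell voxel is flipped in a
#'   rater's mask (default 0.05).
#' @param n_bilateral number of subjects given bilateral (mirrored) damage,
#'   for testing the VLSM exclusion rule (default 0).
#' @param seed integer master seed; the entire cohort is reproducible
#'   from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape = c(32L, 38L, 32L),
                          voxel_size_mm = c(2, 2, 2),
                          n_subjects = 39L,
                          p_left = 21 / 39,
                          lesion_size_range = c(100L, 6000L),
                          critical_center = c(24L, 12L, 16L),
                          critical_radii = c(5, 7, 5),
                          effect_beta = 45,
                          baseline_percent = 95,
                          subject_sigma = 3,
                          n_trials = 10L,
                          n_raters = 4L,
                          rater_dilate_p = 0.3,
                          rater_erode_p = 0.3,
                          rater_flip_p = 0.05,
                          n_bilateral = 0L,
                          seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_subjects = as.integer(n_subjects),
              p_left = p_left,
              lesion_size_range = as.integer(lesion_size_range),
              critical_center = as.integer(critical_center),
              critical_radii = as.numeric(critical_radii),
              effect_beta = effect_beta,
              baseline_percent = baseline_percent,
              subject_sigma = subject_sigma,
              n_trials = as.integer(n_trials),
              n_raters = as.integer(n_raters),
              rater_dilate_p = rater_dilate_p,
              rater_erode_p = rater_erode_p,
              rater_flip_p = rater_flip_p,
              n_bilateral = as.integer(n_bilateral),
              seed = as.integer(seed))
  if (cfg$p_left < 0 || cfg$p_left > 1) stop("`p_left` must be in [0,1]")
  if (cfg$effect_beta < 0) stop("`effect_beta` must be >= 0")
  if (cfg$baseline_percent - cfg$effect_beta < 0)
    stop("baseline - effect_beta must be >= 0")
  if (cfg$n_raters < 3L || cfg$n_raters > 4L)
    stop("`n_raters` must be 3 or 4")
  if (cfg$lesion_size_range[1L] < 1L ||
      cfg$lesion_size_range[2L] < cfg$lesion_size_range[1L])
    stop("invalid `lesion_size_range`")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> n=%d subjects on %s grid, seed %d\n",
                     "  effect_beta=%g, baseline=%g%%, sigma=%g, ",
                     "%d raters\n"),
              x$n_subjects, paste(x$grid_shape, collapse = "x"), x$seed,
              x$effect_beta, x$baseline_percent, x$subject_sigma,
              x$n_raters))
  invisible(x)
}

cohort_grid <- function(config) {
  template_grid(config$grid_shape, config$voxel_size_mm)
}

#' Ground-truth critical region of a cohort configuration
#'
#' The compact ellipsoid in the right posterior hemisphere whose damage
#' drives the planted deficit.
#'
#' @param config a [cohort_config()].
#' @return A [mask_volume()].
#' @export
critical_region_mask <- function(config) {
  d <- config$grid_shape
  cc <- config$critical_center
  cr <- config$critical_radii
  i <- slice.index(array(0, d), 1L)
  j <- slice.index(array(0, d), 2L)
  k <- slice.index(array(0, d), 3L)
  inside <- ((i - cc[1]) / cr[1])^2 + ((j - cc[2]) / cr[2])^2 +
    ((k - cc[3]) / cr[3])^2 <= 1
  mask_volume(array(as.integer(inside), d), cohort_grid(config))
}

# allowed lesion box for a hemisphere: posterior half, one voxel clear of
# the midline so rater jitter cannot cross it
lesion_box <- function(config, side) {
  d <- config$grid_shape
  half <- d[1L] %/% 2L
  x <- if (side == "left") seq_len(half - 1L) else (half + 2L):d[1L]
  list(x = x, y = seq_len(d[2L] %/% 2L), z = seq_len(d[3L]))
}

#' Sample one synthetic lesion
#'
#' Draws a lesion side (left with probability `p_left`), a target size
#' log-uniform within `lesion_size_range`, and a shape formed from 1-3
#' random ellipsoids confined to the chosen hemisphere's posterior half.
#' The lesion is exactly the target number of voxels closest (in scaled
#' ellipsoid distance) to the sampled blob centers, so sizes always fall in
#' the configured range. Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index (seed sub-stream).
#' @return List with `mask` ([mask_volume()]) and `side`.
#' @export
sample_lesion <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(derive_seed(config$seed, 1L, subject_index), {
    side <- if (stats::runif(1) < config$p_left) "left" else "right"
    rng <- config$lesion_size_range
    box <- lesion_box(config, side)
    box_n <- length(box$x) * length(box$y) * length(box$z)
    size <- round(exp(stats::runif(1, log(rng[1L]), log(rng[2L]))))
    size <- min(max(size, rng[1L]), rng[2L], box_n)
    k <- sample.int(3L, 1L)
    w <- stats::runif(k); w <- w / sum(w)
    centers <- matrix(0, k, 3)
    radii <- matrix(0, k, 3)
    for (e in seq_len(k)) {
      # foci are placed independently: multifocal posterior lesions
      centers[e, ] <- c(sample(box$x, 1L), sample(box$y, 1L),
                        sample(box$z, 1L))
      rbar <- (3 * w[e] * size / (4 * pi))^(1 / 3)
      radii[e, ] <- pmax(rbar * exp(stats::rnorm(3, 0, 0.2)), 1)
    }
    d <- config$grid_shape
    i <- slice.index(array(0, d), 1L)
    j <- slice.index(array(0, d), 2L)
    kk <- slice.index(array(0, d), 3L)
    field <- array(Inf, d)
    for (e in seq_len(k)) {
      de <- ((i - centers[e, 1]) / radii[e, 1])^2 +
        ((j - centers[e, 2]) / radii[e, 2])^2 +
        ((kk - centers[e, 3]) / radii[e, 3])^2
      field <- pmin(field, de)
    }
    allowed <- array(FALSE, d)
    allowed[box$x, box$y, box$z] <- TRUE
    field[!allowed] <- Inf
    chosen <- order(field)[seq_len(size)]
    m <- array(0L, d)
    m[chosen] <- 1L
    list(mask = mask_volume(m, cohort_grid(config)), side = side)
  })
}

#' Simulate independent rater delineations of a lesion
#'
#' Each rater's mask is the true lesion, optionally dilated or eroded by one
#' voxel (26-neighbourhood), with a small fraction of boundary-shell voxels
#' flipped. At the default jitter the 2-of-n consensus recovers the truth
#' with Dice >= 0.8.
#'
#' @param true_mask ground-truth [mask_volume()] (non-empty).
#' @param config a [cohort_config()].
#' @param subject_index seed sub-stream index.
#' @return A [rater_set()].
#' @export
simulate_raters <- function(true_mask, config, subject_index = 0L) {
  stopifnot(inherits(true_mask, "mask_volume"))
  if (mask_voxel_count(true_mask) == 0L) stop("true lesion mask is empty")
  with_local_seed(derive_seed(config$seed, 2L, subject_index), {
    dil <- dilate1(true_mask$data)
    ero <- erode1(true_mask$data)
    shell <- which(dil == 1L & ero == 0L)
    masks <- lapply(seq_len(config$n_raters), function(r) {
      u <- stats::runif(1)
      m <- if (u < config$rater_dilate_p) dil
           else if (u < config$rater_dilate_p + config$rater_erode_p) ero
           else true_mask$data
      flip <- shell[stats::runif(length(shell)) < config$rater_flip_p]
      m[flip] <- 1L - m[flip]
      mask_volume(m, true_mask$grid)
    })
    rater_set(masks, subject_id = paste0("sub", subject_index))
  })
}

#' Simulate 2AFC trial blocks for one subject and task
#'
#' Applies the planted lesion-deficit model (see [cohort_config()]) to the
#' subject's damage fraction of the critical region (computed after
#' mirroring the lesion to the right hemisphere) and draws binomial correct
#' counts per condition. For the contrast task, the low-contrast conditions
#' (1/5/10%) are generated near chance (latent 55%) irrespective of damage,
#' mirroring the empirical finding that residual vision is demonstrable
#' mainly at high contrast; scoring excludes them anyway.
#'
#' @param lesion the subject's lesion [mask_volume()].
#' @param config a [cohort_config()].
#' @param task `"contrast"`, `"motion"` or `"faceplace"`.
#' @param subject_index seed sub-stream index.
#' @param critical optional precomputed [critical_region_mask()].
#' @return List with `blocks` (trial-block data.frame), `damage_fraction`,
#'   `p_latent` (latent detection probability in [0.5, 1]).
#' @export
simulate_behavior <- function(lesion, config, task, subject_index = 0L,
                              critical = NULL) {
  stopifnot(inherits(lesion, "mask_volume"))
  if (is.null(critical)) critical <- critical_region_mask(config)
  # hemisphere-normalize: the union with the mirror image covers the right
  norm <- mask_volume(
    array(as.integer(lesion$data | flip_hemisphere(lesion)$data),
          dim = dim(lesion$data)), lesion$grid)
  df <- damage_fraction(critical, norm)
  task_stream <- match(task, c("contrast", "motion", "faceplace"))
  if (is.na(task_stream)) stop("unknown task: ", task)
  with_local_seed(derive_seed(config$seed, 10L + task_stream, subject_index), {
    z <- stats::rnorm(1)
    pct <- config$baseline_percent - config$effect_beta * df +
      config$subject_sigma * z
    p_latent <- min(max(pct, 50), 100) / 100
    conds <- switch(task,
      contrast = c("1", "5", "10", "50", "100"),
      motion = c("4", "8", "20", "32"),
      faceplace = c("faces", "places"))
    p_cond <- if (task == "contrast")
      ifelse(conds %in% c("50", "100"), p_latent, 0.55) else
      rep(p_latent, length(conds))
    blocks <- trial_block(task, conds, rep(config$n_trials, length(conds)),
                          stats::rbinom(length(conds), config$n_trials,
                                        p_cond))
    list(blocks = blocks, damage_fraction = df, p_latent = p_latent)
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces, for every subject: a ground-truth lesion, noisy rater
#' delineations, the 2-of-n consensus mask, and trial blocks for all three
#' detection tasks under the planted deficit model. The first `n_bilateral`
#' subjects receive mirrored bilateral damage (for exclusion-rule tests).
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return List of class `synthetic_cohort` with `subjects` (list of
#'   [subject_record()] whose `lesion` is the *consensus* mask), `truth`
#'   (`critical_mask`, `true_masks`, `damage_fractions`, `latent` table),
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  critical <- critical_region_mask(config)
  subjects <- vector("list", config$n_subjects)
  true_masks <- vector("list", config$n_subjects)
  dfs <- numeric(config$n_subjects)
  latent <- vector("list", 0L)
  for (s in seq_len(config$n_subjects)) {
    id <- sprintf("sub%02d", s)
    les <- sample_lesion(config, s)
    mask <- les$mask; side <- les$side
    if (s <= config$n_bilateral) {
      mask <- mask_volume(
        array(as.integer(mask$data | flip_hemisphere(mask)$data),
              dim = dim(mask$data)), mask$grid)
      side <- "bilateral"
    }
    raters <- simulate_raters(mask, config, s)
    raters$subject_id <- id
    consensus <- consensus_mask(raters)
    beh <- vector("list", 3L)
    tasks <- c("contrast", "motion", "faceplace")
    for (t in seq_along(tasks)) {
      sim <- simulate_behavior(mask, config, tasks[t], s, critical)
      beh[[t]] <- sim$blocks
      dfs[s] <- sim$damage_fraction
      latent[[length(latent) + 1L]] <- data.frame(
        subject_id = id, task = tasks[t], p_latent = sim$p_latent,
        stringsAsFactors = FALSE)
    }
    true_masks[[s]] <- mask
    subjects[[s]] <- subject_record(id, consensus, side,
                                    behavior = do.call(rbind, beh),
                                    raters = raters)
  }
  names(true_masks) <- names(dfs) <-
    vapply(subjects, function(x) x$subject_id, "")
  structure(list(subjects = subjects,
                 truth = list(critical_mask = critical,
                              true_masks = true_masks,
                              damage_fractions = dfs,
                              latent = do.call(rbind, latent)),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  sides <- table(vapply(x$subjects, function(s) s$side, ""))
  cat(sprintf("<synthetic_cohort> n=%d (%s), seed %d\n",
              length(x$subjects),
              paste(names(sides), sides, sep = "=", collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject rater and consensus masks as NIfTI, one behavior TSV,
#' and a YAML manifest of the true generator parameters and per-subject
#' ground truth (side, lesion size, critical damage fraction). The critical
#' region itself is written as `critical_region.nii.gz`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  beh <- vector("list", 0L)
  for (s in cohort$subjects) {
    write_mask(s$lesion,
               file.path(dir, "masks",
                         paste0(s$subject_id, "_consensus.nii.gz")))
    for (r in seq_along(s$raters$masks))
      write_mask(s$raters$masks[[r]],
                 file.path(dir, "masks",
                           sprintf("%s_rater%d.nii.gz", s$subject_id, r)))
    b <- s$behavior
    b <- cbind(subject_id = s$subject_id, b)
    beh[[length(beh) + 1L]] <- b
  }
  write_behavior_tsv(do.call(rbind, beh), file.path(dir, "behavior.tsv"))
  write_mask(cohort$truth$critical_mask,
             file.path(dir, "critical_region.nii.gz"))
  cfg <- unclass(cohort$config)
  yaml::write_yaml(list(
    config = cfg,
    subjects = lapply(cohort$subjects, function(s) list(
      subject_id = s$subject_id, side = s$side,
      consensus_voxels = mask_voxel_count(s$lesion),
      critical_damage_fraction =
        unname(cohort$truth$damage_fractions[s$subject_id])))),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
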