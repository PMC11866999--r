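#' Default run configuration for the full analysis
#'
#' Collects the paths and analysis parameters of the end-to-end pipeline.
#' Parameter defaults are the study's printed values: consensus threshold
#' 1.9 (at least two raters), atlas thresholds 50% (V1), 30% (V4), 10%
#' (hMT+/V5), at least 3 lesioned subjects per analyzed voxel, FDR q = 0.05,
#' left-lesion flipping and bilateral exclusion enabled.
#'
#' @param mask_dir directory of per-subject masks, either
#'   `<id>_rater<k>.nii.gz` sets (consensus computed here) or
#'   `<id>_consensus.nii.gz`.
#' @param behavior_tsv behavioral trial TSV (`subject_id`, `task`,
#'   `condition`, `n_trials`, `n_correct`).
#' @param out_dir output directory.
#' @param atlas named character vector of ROI NIfTI paths (names are ROI
#'   labels), or `NULL` to skip ROI damage and correlations.
#' @param consensus_threshold rater-sum threshold (default 1.9).
#' @param atlas_thresholds named list of atlas threshold percents per ROI.
#' @param vlsm_task task whose scores feed the VLSM (default "contrast").
#' @param fdr_q FDR level (default 0.05).
#' @param min_subjects voxel inclusion threshold (default 3).
#' @param flip_left,exclude_bilateral hemisphere-normalization flags.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mask_dir, behavior_tsv, out_dir, atlas = NULL,
                       consensus_threshold = 1.9,
                       atlas_thresholds = list(V1 = 50, V4 = 30,
                                               `hMT+/V5` = 10),
                       vlsm_task = "contrast", fdr_q = 0.05,
                       min_subjects = 3L, flip_left = TRUE,
                       exclude_bilateral = TRUE) {
  structure(list(mask_dir = mask_dir, behavior_tsv = behavior_tsv,
                 out_dir = out_dir, atlas = atlas,
                 consensus_threshold = consensus_threshold,
                 atlas_thresholds = atlas_thresholds,
                 vlsm_task = vlsm_task, fdr_q = fdr_q,
                 min_subjects = as.integer(min_subjects),
                 flip_left = flip_left,
                 exclude_bilateral = exclude_bilateral),
            class = "run_config")
}

#' Load subject records (consensus lesions + behavior) from disk
#'
#' Builds one [subject_record()] per subject found in `mask_dir`. Subjects
#' with rater files get a consensus mask computed at `consensus_threshold`;
#' otherwise a precomputed `_consensus` mask is required. Lesion side is
#' inferred from mask geometry. Every subject must appear in the behavior
#' table and vice versa.
#'
#' @inheritParams run_config
#' @return List of [subject_record()] objects.
#' @export
load_subjects <- function(mask_dir, behavior_tsv,
                          consensus_threshold = 1.9) {
  files <- list.files(mask_dir, pattern = "\\.nii(\\.gz)?$")
  ids <- unique(sub("_(rater[0-9]+|consensus)\\.nii(\\.gz)?$", "", files))
  ids <- sort(ids)
  if (length(ids) == 0L) stop("no mask files found in ", mask_dir)
  behavior <- read_behavior_tsv(behavior_tsv)
  beh_ids <- unique(behavior$subject_id)
  if (length(setdiff(ids, beh_ids)) > 0L)
    stop("subject(s) with masks but no behavior: ",
         paste(setdiff(ids, beh_ids), collapse = ", "))
  if (length(setdiff(beh_ids, ids)) > 0L)
    stop("subject(s) with behavior but no mask: ",
         paste(setdiff(beh_ids, ids), collapse = ", "))
  lapply(ids, function(id) {
    rater_files <- sort(files[grepl(paste0("^", id, "_rater[0-9]+\\.nii"),
                                    files)])
    raters <- NULL
    if (length(rater_files) >= 3L) {
      raters <- rater_set(lapply(file.path(mask_dir, rater_files), read_mask),
                          subject_id = id,
                          rater_ids = sub("\\.nii(\\.gz)?$", "", rater_files))
      lesion <- consensus_mask(raters, consensus_threshold)
    } else {
      cfile <- file.path(mask_dir, paste0(id, "_consensus.nii.gz"))
      if (!file.exists(cfile))
        cfile <- file.path(mask_dir, paste0(id, "_consensus.nii"))
      if (!file.exists(cfile))
        stop("subject ", id, ": need >= 3 rater masks or a consensus mask")
      lesion <- read_mask(cfile)
    }
    subject_record(id, lesion,
                   behavior = behavior[behavior$subject_id == id, ,
                                       drop = FALSE],
                   raters = raters)
  })
}

#' Run the complete lesion-analysis pipeline
#'
#' Executes, in order: consensus masking, behavioral scoring, ROI damage
#' quantification (when an atlas is configured), the damage-behavior
#' Spearman correlation grid with Bonferroni control, and the dTLVC-weighted
#' VLSM with FDR correction and cluster extraction. Every intermediate
#' artifact is written under `out_dir` along with a machine-readable
#' `manifest.yaml` recording parameters and subject exclusions. The run is
#' deterministic: identical inputs give identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `subjects`, `scores`, `damage`,
#'   `correlations`, `vlsm`, and `out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  subjects <- stage("consensus", load_subjects(config$mask_dir,
                                               config$behavior_tsv,
                                               config$consensus_threshold))
  cdir <- file.path(config$out_dir, "consensus")
  dir.create(cdir, showWarnings = FALSE)
  for (s in subjects)
    write_mask(s$lesion, file.path(cdir, paste0(s$subject_id, ".nii.gz")))
  behavior <- read_behavior_tsv(config$behavior_tsv)
  scores <- stage("scoring", score_behavior_table(behavior))
  write_behavior_tsv(scores, file.path(config$out_dir, "scores.tsv"))
  damage <- NULL
  correlations <- NULL
  if (!is.null(config$atlas)) {
    rois <- stage("atlas", lapply(names(config$atlas), function(nm)
      read_roi(config$atlas[[nm]], nm)))
    damage <- stage("roi-damage",
                    damage_table(subjects, rois, config$atlas_thresholds))
    write_damage_table(damage, file.path(config$out_dir, "damage.tsv"))
    thr <- unlist(config$atlas_thresholds)
    correlations <- stage("correlate",
                          correlation_grid(damage, scores, thresholds = thr))
    utils::write.table(correlations,
                       file.path(config$out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  vlsm <- stage("vlsm", run_vlsm(
    subjects, task = config$vlsm_task, q = config$fdr_q,
    min_subjects = config$min_subjects, flip_left = config$flip_left))
  write_vlsm_result(vlsm, file.path(config$out_dir, "vlsm"))
  yaml::write_yaml(list(
    parameters = list(consensus_threshold = config$consensus_threshold,
                      atlas_thresholds = config$atlas_thresholds,
                      vlsm_task = config$vlsm_task, fdr_q = config$fdr_q,
                      min_subjects = config$min_subjects,
                      flip_left = config$flip_left,
                      exclude_bilateral = config$exclude_bilateral),
    n_subjects = length(subjects),
    vlsm_excluded = as.list(vlsm$excluded),
    n_vlsm_subjects = vlsm$n_subjects),
    file.path(config$out_dir, "manifest.yaml"))
  invisible(list(subjects = subjects, scores = scores, damage = damage,
                 correlations = correlations, vlsm = vlsm,
                 out_dir = config$out_dir))
}
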