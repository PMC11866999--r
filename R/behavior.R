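#' Trial blocks for 2AFC detection tasks
#'
#' One row per (task, condition) block, holding the number of trials and the
#' number answered correctly. Tasks follow the study design: `contrast`
#' (drifting Gabor at 1/5/10/50/100% contrast, 10 trials each), `motion`
#' (moving dots at four speeds), and `faceplace` (face and place images).
#' Chance performance is 50% in all tasks.
#'
#' @param task task label: `"contrast"`, `"motion"` or `"faceplace"`.
#' @param condition character condition labels (contrast level, speed, or
#'   image category).
#' @param n_trials positive integer trial counts.
#' @param n_correct integer correct counts, `0 <= n_correct <= n_trials`.
#' @return A `data.frame` with one row per block.
#' @export
trial_block <- function(task, condition, n_trials, n_correct) {
  n_trials <- as.integer(n_trials)
  n_correct <- as.integer(n_correct)
  if (any(n_trials < 1L)) stop("`n_trials` must be positive")
  if (any(n_correct < 0L) || any(n_correct > n_trials))
    stop("`n_correct` must satisfy 0 <= n_correct <= n_trials")
  data.frame(task = as.character(task), condition = as.character(condition),
             n_trials = n_trials, n_correct = n_correct,
             stringsAsFactors = FALSE)
}

#' Pool trial blocks across conditions
#'
#' Sums trials and correct responses over the selected blocks, e.g. pooling
#' the two high-contrast levels, all motion speeds, or faces with places.
#'
#' @param blocks `data.frame` of trial blocks (one task).
#' @param keep `"all"` or a character vector of condition labels to retain.
#' @return A single pooled trial-block row.
#' @export
collapse_conditions <- function(blocks, keep = "all") {
  stopifnot(is.data.frame(blocks), nrow(blocks) >= 1L)
  if (length(unique(blocks$task)) != 1L)
    stop("all blocks must share one task")
  sel <- if (identical(keep, "all")) rep(TRUE, nrow(blocks))
         else blocks$condition %in% keep
  if (!any(sel)) stop("condition filter selects no blocks")
  kept <- blocks[sel, , drop = FALSE]
  trial_block(kept$task[1L], paste(sort(unique(kept$condition)),
                                   collapse = "+"),
              sum(kept$n_trials), sum(kept$n_correct))
}

#' Exact binomial test against chance for 2AFC performance
#'
#' One-sided exact tail of Binomial(n, 1/2) in the direction of the
#' observation: the upper tail P(X >= k) when percent correct is at or above
#' 50, the lower tail P(X <= k) otherwise. Performance is `above_chance`
#' when the upper tail is below `alpha`, `below_chance` when the lower tail
#' is, and `at_chance` otherwise. With 20 trials this makes proportions
#' >= 75% and <= 25% the significant ones.
#'
#' @param n_correct number of correct trials.
#' @param n_trials total trials (>= 1).
#' @param alpha one-sided significance level (default 0.05).
#' @return List with `p_value` (the directional tail) and `category`
#'   (`"above_chance"`, `"at_chance"` or `"below_chance"`).
#' @examples
#' binomial_chance_test(15, 20)$category # above_chance
#' binomial_chance_test(14, 20)$category # at_chance
#' @export
binomial_chance_test <- function(n_correct, n_trials, alpha = 0.05) {
  n_correct <- as.integer(n_correct)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L || n_correct < 0L || n_correct > n_trials)
    stop("invalid counts: need 0 <= n_correct <= n_trials, n_trials >= 1")
  upper <- stats::pbinom(n_correct - 1L, n_trials, 0.5, lower.tail = FALSE)
  lower <- stats::pbinom(n_correct, n_trials, 0.5)
  if (n_correct * 2L >= n_trials) {   # percent >= 50: upper tail
    list(p_value = upper,
         category = if (upper < alpha) "above_chance" else "at_chance")
  } else {
    list(p_value = lower,
         category = if (lower < alpha) "below_chance" else "at_chance")
  }
}

#' Floor sub-chance, non-significant scores at 50%
#'
#' Any percent correct below 50 that is not statistically different from
#' chance is assigned 50, a conservative adjustment that prevents spurious
#' correlations between damage and nominally sub-chance scores. Significant
#' below-chance scores are retained as observed.
#'
#' @param score a `behavior_score` list (see [score_task()]) with
#'   `percent_raw` and `category` populated.
#' @return The score with `percent_adjusted` set.
#' @export
adjust_floor <- function(score) {
  stopifnot(!is.null(score$percent_raw), !is.null(score$category))
  score$percent_adjusted <-
    if (score$percent_raw < 50 && score$category == "at_chance") 50
    else score$percent_raw
  score
}

task_keep_rule <- function(task_policy) {
  switch(task_policy,
    contrast = c("50", "100"),  # only high contrasts quantify residual vision
    motion = "all",
    faceplace = "all",
    stop("unknown task policy: ", task_policy))
}

#' Score a subject's 2AFC task
#'
#' Applies the task's pooling rule (contrast: high contrasts 50 and 100%
#' only; motion: all speeds; faceplace: faces and places pooled), tests the
#' pooled count against chance with the exact binomial, and applies the
#' floor-at-50 adjustment.
#'
#' @param blocks `data.frame` of trial blocks for one task and subject.
#' @param task_policy task label; defaults to the blocks' task.
#' @param alpha one-sided significance level for the chance test.
#' @return A `behavior_score` list: `task`, `n_trials`, `n_correct`,
#'   `percent_raw`, `p_binomial`, `category`, `percent_adjusted`.
#' @export
score_task <- function(blocks, task_policy = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(blocks), nrow(blocks) >= 1L)
  if (is.null(task_policy)) task_policy <- blocks$task[1L]
  pooled <- collapse_conditions(blocks, task_keep_rule(task_policy))
  test <- binomial_chance_test(pooled$n_correct, pooled$n_trials, alpha)
  score <- list(task = task_policy,
                n_trials = pooled$n_trials, n_correct = pooled$n_correct,
                percent_raw = 100 * pooled$n_correct / pooled$n_trials,
                p_binomial = test$p_value, category = test$category)
  adjust_floor(score)
}

#' Score every subject and task in a behavioral table
#'
#' @param behavior `data.frame` with columns `subject_id`, `task`,
#'   `condition`, `n_trials`, `n_correct` (the TSV interchange format).
#' @param alpha one-sided significance level.
#' @return A `data.frame` with one row per (subject, task): the input keys
#'   plus `percent_raw`, `p_binomial`, `category`, `percent_adjusted`.
#' @export
score_behavior_table <- function(behavior, alpha = 0.05) {
  need <- c("subject_id", "task", "condition", "n_trials", "n_correct")
  if (!all(need %in% names(behavior)))
    stop("behavior table needs columns: ", paste(need, collapse = ", "))
  keys <- unique(behavior[c("subject_id", "task")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- behavior[behavior$subject_id == keys$subject_id[i] &
                    behavior$task == keys$task[i], , drop = FALSE]
    sc <- score_task(sub, keys$task[i], alpha)
    data.frame(subject_id = keys$subject_id[i], task = keys$task[i],
               n_trials = sc$n_trials, n_correct = sc$n_correct,
               percent_raw = sc$percent_raw, p_binomial = sc$p_binomial,
               category = sc$category,
               percent_adjusted = sc$percent_adjusted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read/write behavioral TSV tables
#'
#' The interchange format is tab-separated with header columns
#' `subject_id`, `task`, `condition`, `n_trials`, `n_correct`; scored tables
#' append `percent_raw`, `p_binomial`, `category`, `percent_adjusted`.
#'
#' @param path TSV path.
#' @return `read_behavior_tsv()`: the table; `write_behavior_tsv()`: `path`.
#' @export
read_behavior_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(condition = "character"))
  tab
}

#' @rdname read_behavior_tsv
#' @param tab behavioral table to write.
#' @export
write_behavior_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
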