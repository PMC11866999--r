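#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (ties allowed). The
#' p-value is exact for n <= 9 — a full enumeration of all n! rank
#' permutations, two-sided — and otherwise uses the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) on n - 2 df. An approximate Fisher-z
#' confidence interval (n - 3 denominator) is attached; for Spearman's rho
#' it should be read as indicative only.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param alpha_adjusted significance level, typically Bonferroni-adjusted
#'   for the family of correlations (default 0.05).
#' @return List with `rho`, `p_value`, `n`, `alpha_adjusted`, `significant`,
#'   `conf_low`, `conf_high`, `method`.
#' @export
spearman_cor <- function(x, y, alpha_adjusted = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 4L) stop("need n >= 4")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  rx <- rank(x); ry <- rank(y)
  rho <- if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("a constant vector has no rank correlation")
  } else stats::cor(rx, ry)
  if (n <= 9L) {
    # exact two-sided permutation p over all n! orderings of y's ranks
    perms <- permutations_all(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(pr) stats::cor(rx, ry[pr]))
    p <- mean(abs(rhos) >= obs - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), n - 2)
    method <- "t approximation"
  }
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(rho = rho, p_value = p, n = n, alpha_adjusted = alpha_adjusted,
       significant = p < alpha_adjusted,
       conf_low = tanh(z - hw), conf_high = tanh(z + hw), method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 keeps this small
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}

#' Bonferroni-adjusted per-test alpha
#'
#' Family alpha divided by the number of comparisons, rounded as reported:
#' 0.05/3 at 4 decimals is 0.0167 (three tasks), 0.05/9 at 3 decimals is
#' 0.006 (three areas x three tasks).
#'
#' @param m number of comparisons (>= 1).
#' @param family_alpha family-wise alpha (default 0.05).
#' @param decimals decimal places to round to; `NULL` for no rounding.
#' @return The per-comparison alpha.
#' @export
bonferroni_alpha <- function(m, family_alpha = 0.05, decimals = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  a <- family_alpha / m
  if (!is.null(decimals)) a <- round(a, decimals)
  a
}

#' Friedman test across within-subject conditions
#'
#' Nonparametric repeated-measures comparison on within-subject ranks
#' (mid-ranks for ties), used e.g. to check that ROI damage fractions do not
#' depend on the atlas threshold. Delegates to [stats::friedman.test()].
#'
#' @param m numeric matrix, subjects in rows, conditions in columns
#'   (>= 2 each, no missing cells).
#' @return List with `statistic` (Friedman chi-square), `df`, `p_value`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 conditions")
  if (anyNA(m)) stop("missing cells not allowed")
  ranks <- t(apply(m, 1L, rank))
  if (all(abs(colSums(ranks) - mean(colSums(ranks))) < 1e-12)) {
    # rank-identical conditions carry no signal; the tie-corrected form is
    # 0/0 here but the statistic is exactly 0
    return(list(statistic = 0, df = ncol(m) - 1L, p_value = 1))
  }
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Signed-rank test on the non-zero paired differences (e.g. face vs place
#' detection), exact for <= 25 informative pairs without ties and the normal
#' approximation otherwise, via [stats::wilcox.test()]. If every pair is
#' tied the test is degenerate and reported as such rather than erroring.
#'
#' @param a,b paired numeric vectors.
#' @return List with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n_informative`, `degenerate`.
#' @export
wilcoxon_paired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("`a` and `b` must be paired")
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_informative = 0L, degenerate = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25L,
                       correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_informative = length(nz), degenerate = FALSE)
}

#' Linear vs quadratic fit comparison (extra sum-of-squares F-test)
#'
#' Fits least-squares polynomials of degree 1 and 2 and compares their
#' residual sums of squares with F = ((SS1 - SS2)/1) / (SS2/(n - 3)). The
#' quadratic is preferred when the F-test is significant at 0.05.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param alpha significance level for preferring the quadratic.
#' @return List with `ss_linear`, `ss_quadratic`, `F`, `p_value`,
#'   `preferred` (`"linear"` or `"quadratic"`), and the two `lm` fits.
#' @export
fit_comparison <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 4L) stop("need paired vectors with n >= 4")
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + I(x^2))
  ss1 <- sum(stats::resid(f1)^2)
  ss2 <- sum(stats::resid(f2)^2)
  Fstat <- ((ss1 - ss2) / 1) / (ss2 / (n - 3))
  p <- stats::pf(Fstat, 1, n - 3, lower.tail = FALSE)
  list(ss_linear = ss1, ss_quadratic = ss2, F = Fstat, p_value = p,
       preferred = if (!is.nan(p) && p < alpha) "quadratic" else "linear",
       fit_linear = f1, fit_quadratic = f2)
}

#' Correlation grid between ROI damage and task performance
#'
#' Joins a damage table with scored behavior on `subject_id` and computes,
#' for each (ROI, task) pair, the Spearman correlation between the damage
#' fraction (at each ROI's designated threshold) and the floor-adjusted
#' percent correct. The per-test alpha is Bonferroni-corrected for the
#' number of (ROI, task) pairs in the grid.
#'
#' @param damage data.frame from [damage_table()], already restricted to
#'   one threshold per ROI (or pass `thresholds` to select).
#' @param scores data.frame from [score_behavior_table()].
#' @param thresholds optional named vector selecting, per ROI, which
#'   threshold's rows to use.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return data.frame with one row per (roi, task): `rho`, `p_value`, `n`,
#'   `alpha_adjusted`, `significant`.
#' @export
correlation_grid <- function(damage, scores, thresholds = NULL,
                             family_alpha = 0.05) {
  if (!is.null(thresholds)) {
    sel <- mapply(function(r, t) {
      !is.na(match(r, names(thresholds))) & t == thresholds[[r]]
    }, damage$roi, damage$threshold)
    damage <- damage[sel, , drop = FALSE]
  }
  rois <- unique(damage$roi)
  tasks <- unique(scores$task)
  m <- length(rois) * length(tasks)
  alpha <- bonferroni_alpha(m, family_alpha)
  rows <- vector("list", 0L)
  for (r in rois) {
    dr <- damage[damage$roi == r, , drop = FALSE]
    if (length(unique(dr$threshold)) > 1L)
      stop("multiple thresholds remain for ROI '", r,
           "'; pass `thresholds` to disambiguate")
    for (tk in tasks) {
      st <- scores[scores$task == tk, , drop = FALSE]
      missing_beh <- setdiff(dr$subject_id, st$subject_id)
      if (length(missing_beh) > 0L)
        stop("subject(s) in damage table but not scored for task '", tk,
             "': ", paste(missing_beh, collapse = ", "))
      j <- merge(dr[c("subject_id", "fraction")],
                 st[c("subject_id", "percent_adjusted")], by = "subject_id")
      if (nrow(j) < 4L)
        stop("fewer than 4 joined subjects for ", r, " x ", tk)
      sc <- spearman_cor(j$fraction, j$percent_adjusted, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, task = tk, rho = sc$rho, p_value = sc$p_value, n = sc$n,
        alpha_adjusted = alpha, significant = sc$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
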