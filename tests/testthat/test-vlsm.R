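test_that("inclusion mask keeps voxels lesioned in >= min_subjects", {
  g <- template_grid(c(5, 1, 1))
  masks <- lapply(1:4, function(s) {
    d <- array(0L, g$shape)
    d[seq_len(s), 1, 1] <- 1L   # subject s lesions voxels 1..s
    mask_volume(d, g)
  })
  # counts at voxels 1..5 are therefore 4,3,2,1,0
  ov <- overlap_map(masks)
  expect_identical(as.vector(ov$counts), c(4L, 3L, 2L, 1L, 0L))
  inc <- build_inclusion_mask(ov, 3)
  expect_identical(as.vector(inc$data), c(1L, 1L, 0L, 0L, 0L))
  inc1 <- build_inclusion_mask(ov, 1)
  expect_identical(as.vector(inc1$data), as.integer(ov$counts >= 1))
  # random cohort vs counting oracle
  g8 <- small_grid()
  rmasks <- lapply(1:9, function(s) random_mask(g8, p = 0.3, seed = 70 + s))
  rov <- overlap_map(rmasks)
  rinc <- build_inclusion_mask(rov, 3)
  expect_identical(rinc$data, array(as.integer(rov$counts >= 3L), g8$shape))
})

test_that("dTLVC weights scale rows to unit full-grid norm", {
  g <- small_grid()
  masks <- lapply(1:8, function(s) random_mask(g, p = 0.3, seed = 80 + s))
  inc <- build_inclusion_mask(overlap_map(masks), 2)
  lm_ <- lesion_matrix(masks, inc)
  w <- dtlvc_weights(lm_)
  for (s in 1:8) {
    V <- mask_voxel_count(masks[[s]])
    # elementwise l / sqrt(V) oracle
    expect_equal(w$values[s, ], lm_$values[s, ] / sqrt(V), tolerance = 1e-12)
    # full-grid norm: sum over ALL voxels of (1/sqrt(V))^2 * lesion status
    expect_equal(sum((masks[[s]]$data / sqrt(V))^2), 1, tolerance = 1e-12)
  }
  # a subject with V = 4 gets entries of exactly 0.5
  d <- array(0L, g$shape); d[1:4] <- 1L
  m4 <- mask_volume(d, g)
  inc_all <- mask_volume(array(1L, g$shape), g)
  w4 <- dtlvc_weights(lesion_matrix(list(m4, masks[[1]], masks[[2]]), inc_all))
  expect_identical(sort(unique(w4$values[1, ])), c(0, 0.5))
  # empty lesions are rejected
  m0 <- mask_volume(array(0L, g$shape), g)
  expect_error(dtlvc_weights(lesion_matrix(list(m0, m4, m4), inc_all)),
               "empty lesion")
  expect_error(dtlvc_weights(w), "already weighted")
})

test_that("weighting changes statistics but not which voxels are analyzed", {
  g <- small_grid()
  masks <- lapply(1:10, function(s) random_mask(g, p = 0.3, seed = 90 + s))
  inc <- build_inclusion_mask(overlap_map(masks), 3)
  raw <- lesion_matrix(masks, inc)
  wtd <- dtlvc_weights(lesion_matrix(masks, inc))
  expect_identical(raw$voxel_index, wtd$voxel_index)
  y <- demean(withr::with_seed(4, rnorm(10)))
  reg_raw <- voxelwise_regression(raw, y)
  reg_wtd <- voxelwise_regression(wtd, y)
  expect_identical(reg_raw$degenerate, reg_wtd$degenerate)
})

test_that("demean centres vectors and preserves order", {
  expect_equal(demean(c(60, 80, 100)), c(-20, 0, 20))
  expect_equal(demean(rep(7, 5)), rep(0, 5))
  v <- withr::with_seed(8, runif(31, 0, 100))
  expect_equal(mean(demean(v)), 0, tolerance = 1e-12)
  expect_equal(order(demean(v)), order(v))
  expect_error(demean(5), "at least 2")
})

test_that("voxelwise regression matches a per-voxel lm() oracle", {
  g <- template_grid(c(6, 6, 6))
  n <- 20
  masks <- lapply(1:n, function(s) random_mask(g, p = 0.35, seed = 100 + s))
  inc <- build_inclusion_mask(overlap_map(masks), 3)
  lm_ <- dtlvc_weights(lesion_matrix(masks, inc))
  y <- demean(withr::with_seed(5, runif(n, 50, 100)))
  reg <- voxelwise_regression(lm_, y)
  for (v in seq_along(lm_$voxel_index)) {
    x <- lm_$values[, v]
    if (reg$degenerate[v]) {
      expect_equal(reg$p[v], 1)
      next
    }
    fit <- summary(stats::lm(y ~ x))
    tv <- fit$coefficients["x", "t value"]
    expect_equal(reg$stat[v], tv, tolerance = 1e-10)
    expect_equal(reg$p[v], stats::pt(tv, n - 2), tolerance = 1e-10)
  }
})

test_that("regression handles exact fits and constant behavior", {
  g <- template_grid(c(3, 1, 1))
  d1 <- array(c(1L, 0L, 0L), c(3, 1, 1))
  masks <- list(mask_volume(d1, g), mask_volume(1L - d1, g),
                mask_volume(array(c(0L, 1L, 0L), c(3, 1, 1)), g),
                mask_volume(array(c(1L, 1L, 0L), c(3, 1, 1)), g))
  inc <- mask_volume(array(1L, g$shape), g)
  lm_ <- lesion_matrix(masks, inc)
  # behavior exactly -2 * damage at voxel 1: slope -2, p -> 0
  y <- -2 * lm_$values[, 1]
  reg <- voxelwise_regression(lm_, demean(y))
  expect_equal(reg$stat[1], -Inf)
  expect_equal(reg$p[1], 0)
  # constant behavior: zero slopes everywhere, nothing significant
  reg0 <- voxelwise_regression(lm_, demean(rep(80, 4)) + 0)
  expect_true(all(reg0$p[!reg0$degenerate] >= 0.5))
})

test_that("BH FDR reproduces hand-checkable vectors", {
  # all tiny p-values survive
  res <- fdr_correct(rep(0.001, 100), 0.05)
  expect_true(all(res$significant))
  # p(i) = i/100 exactly: all pass at q = 0.05? p(i) <= (i/m) q fails for
  # most; classic staircase where only the full set matters
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  res <- fdr_correct(p, 0.05)
  expect_true(all(res$significant))   # p(i) <= i * 0.01 for every i
  expect_equal(res$threshold_p, 0.05)
  # step-up adjusted values against a manual loop
  pv <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6, 0.74, 0.9)
  res <- fdr_correct(pv, 0.05)
  m <- length(pv)
  ord <- order(pv)
  manual <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * pv[ord[i]])
    manual[ord[i]] <- prev
  }
  expect_equal(res$q_values, manual, tolerance = 1e-12)
  expect_identical(res$significant, manual <= 0.05)
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("clusters match an independent flood-fill oracle", {
  g <- small_grid()
  # two well-separated blobs of 7 and 3 voxels
  d <- array(0L, g$shape)
  d[1:7, 1, 1] <- 1L
  d[1:3, 8, 8] <- 1L
  cl <- extract_clusters(mask_volume(d, g))
  expect_equal(cl$voxel_count, c(7, 3))
  expect_equal(cl$volume_mm3, c(7, 3) * 8)
  expect_equal(nrow(extract_clusters(mask_volume(array(0L, g$shape), g))), 0)
  for (seed in 1:4) {
    for (conn in c(26L, 6L)) {
      m <- random_mask(g, p = 0.2, seed = 200 + seed)
      cl <- extract_clusters(m, connectivity = conn)
      oracle <- flood_fill_components(m$data, conn)
      expect_equal(nrow(cl), max(oracle))
      expect_equal(sort(cl$voxel_count, decreasing = TRUE),
                   sort(as.integer(table(oracle[oracle > 0])),
                        decreasing = TRUE))
      # label partitions agree up to renaming
      labs <- attr(cl, "labels")
      expect_equal(sum(cl$voxel_count), mask_voxel_count(m))
      for (r in seq_len(nrow(cl))) {
        members <- which(labs == r)
        expect_equal(length(unique(oracle[members])), 1L)
      }
    }
  }
})

test_that("run_vlsm excludes bilateral subjects and is deterministic", {
  cfg <- tiny_config(seed = 31, n_bilateral = 1L)
  co <- generate_cohort(cfg)
  res <- run_vlsm(co$subjects, "contrast", min_subjects = 2)
  expect_equal(res$n_subjects, cfg$n_subjects - 1L)
  expect_identical(res$excluded, "sub01")
  res2 <- run_vlsm(co$subjects, "contrast", min_subjects = 2)
  expect_identical(res$stat_map, res2$stat_map)
  expect_identical(res$clusters$voxel_count, res2$clusters$voxel_count)
  # significant voxels always lie inside the inclusion mask, clusters
  # partition the significant mask
  expect_true(all(res$significant_mask$data <= res$inclusion_mask$data))
  expect_equal(sum(res$clusters$voxel_count),
               mask_voxel_count(res$significant_mask))
})

test_that("vlsm results are written with maps, clusters and manifest", {
  co <- generate_cohort(tiny_config(seed = 33))
  res <- run_vlsm(co$subjects, "contrast", min_subjects = 2)
  dir <- file.path(withr::local_tempdir(), "vlsm")
  write_vlsm_result(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("stat.nii.gz", "p.nii.gz", "q.nii.gz", "significant.nii.gz",
      "inclusion.nii.gz", "overlap.nii.gz", "clusters.tsv",
      "manifest.yaml")))))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$n_subjects, res$n_subjects)
  expect_equal(man$significant_voxels, mask_voxel_count(res$significant_mask))
})
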