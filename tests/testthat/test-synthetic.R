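test_that("lesion sampling is deterministic, confined and size-bounded", {
  cfg <- cohort_config(seed = 5)
  a <- sample_lesion(cfg, 3)
  b <- sample_lesion(cfg, 3)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$side, b$side)
  half <- cfg$grid_shape[1] %/% 2
  for (s in 1:25) {
    les <- sample_lesion(cfg, s)
    n <- mask_voxel_count(les$mask)
    expect_gte(n, cfg$lesion_size_range[1])
    expect_lte(n, cfg$lesion_size_range[2])
    xs <- which(apply(les$mask$data, 1, sum) > 0)
    ys <- which(apply(les$mask$data, 2, sum) > 0)
    if (les$side == "left") expect_true(all(xs <= half))
    else expect_true(all(xs > half))
    expect_true(all(ys <= cfg$grid_shape[2] %/% 2))  # posterior half
  }
})

test_that("rater simulation recovers truth through the consensus", {
  cfg <- cohort_config(seed = 9)
  # zero jitter: all raters identical to truth
  cfg0 <- cohort_config(seed = 9, rater_dilate_p = 0, rater_erode_p = 0,
                        rater_flip_p = 0)
  les <- sample_lesion(cfg0, 1)
  rs <- simulate_raters(les$mask, cfg0, 1)
  for (m in rs$masks) expect_identical(m$data, les$mask$data)
  expect_identical(consensus_mask(rs)$data, les$mask$data)
  # default jitter: mean Dice(consensus, truth) >= 0.8 across subjects
  dices <- vapply(1:30, function(s) {
    les <- sample_lesion(cfg, s)
    cons <- consensus_mask(simulate_raters(les$mask, cfg, s))
    dice(cons, les$mask)
  }, 0)
  expect_gte(mean(dices), 0.8)
  # consensus is always a subset of the rater union
  les <- sample_lesion(cfg, 2)
  rs <- simulate_raters(les$mask, cfg, 2)
  cons <- consensus_mask(rs)
  un <- Reduce(`|`, lapply(rs$masks, function(m) m$data == 1L))
  expect_true(all(cons$data <= un))
})

test_that("behavior follows the planted deficit model", {
  cfg <- cohort_config(seed = 13, subject_sigma = 0)
  crit <- critical_region_mask(cfg)
  # no damage: latent probability is the baseline
  g <- cohort_grid(cfg)
  d <- array(0L, cfg$grid_shape); d[2, 2, 25] <- 1L   # far from critical
  sim <- simulate_behavior(mask_volume(d, g), cfg, "contrast", 1)
  expect_equal(sim$damage_fraction, 0)
  expect_equal(sim$p_latent, 0.95)
  # full critical damage at beta 45: latent probability falls to chance
  full <- mask_volume(crit$data, g)
  sim <- simulate_behavior(full, cfg, "contrast", 2)
  expect_equal(sim$damage_fraction, 1)
  expect_equal(sim$p_latent, 0.5)
  # binomial draws have the right mean: 10,000 trials at p* = 0.75
  cfg20 <- cohort_config(seed = 13, subject_sigma = 0, baseline_percent = 75,
                         n_trials = 20L)
  sims <- lapply(1:500, function(i)
    simulate_behavior(mask_volume(d, g), cfg20, "motion", i))
  ks <- unlist(lapply(sims, function(s) s$blocks$n_correct))
  expect_equal(mean(ks) / 20, 0.75, tolerance = 0.01)
})

test_that("left lesions drive the deficit through their mirrored position", {
  cfg <- cohort_config(seed = 13, subject_sigma = 0)
  crit <- critical_region_mask(cfg)
  left <- flip_hemisphere(mask_volume(crit$data, cohort_grid(cfg)))
  sim <- simulate_behavior(left, cfg, "contrast", 3)
  expect_equal(sim$damage_fraction, 1)
})

test_that("generated cohorts are reproducible and contract-valid", {
  cfg <- tiny_config(seed = 17)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(length(co1$subjects), cfg$n_subjects)
  for (s in seq_along(co1$subjects)) {
    expect_identical(co1$subjects[[s]]$lesion$data,
                     co2$subjects[[s]]$lesion$data)
    expect_identical(co1$subjects[[s]]$behavior, co2$subjects[[s]]$behavior)
    beh <- co1$subjects[[s]]$behavior
    expect_true(all(beh$n_correct >= 0 & beh$n_correct <= beh$n_trials))
    expect_setequal(unique(beh$task), c("contrast", "motion", "faceplace"))
  }
  expect_true(all(co1$truth$latent$p_latent >= 0.5 &
                  co1$truth$latent$p_latent <= 1))
})

test_that("planted effect appears as a significant negative correlation", {
  cfg <- cohort_config(seed = 19)
  co <- generate_cohort(cfg)
  scored <- vapply(co$subjects, function(s)
    score_task(s$behavior[s$behavior$task == "contrast", ])$percent_adjusted,
    0)
  sc <- spearman_cor(co$truth$damage_fractions, scored,
                     alpha_adjusted = bonferroni_alpha(3, decimals = 4))
  expect_lt(sc$rho, 0)
  expect_true(sc$significant)
  # with the effect switched off, damage and behavior decouple
  co0 <- generate_cohort(cohort_config(seed = 19, effect_beta = 0))
  scored0 <- vapply(co0$subjects, function(s)
    score_task(s$behavior[s$behavior$task == "contrast", ])$percent_adjusted,
    0)
  expect_lt(abs(spearman_cor(co0$truth$damage_fractions, scored0)$rho), 0.3)
})

test_that("cohorts round-trip to disk with truth manifest", {
  cfg <- tiny_config(seed = 23, n_subjects = 4L)
  co <- generate_cohort(cfg)
  dir <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  expect_true(file.exists(file.path(dir, "critical_region.nii.gz")))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(length(truth$subjects), 4)
  m <- read_mask(file.path(dir, "masks", "sub01_consensus.nii.gz"))
  expect_identical(m$data, co$subjects[[1]]$lesion$data)
  beh <- read_behavior_tsv(file.path(dir, "behavior.tsv"))
  expect_equal(sort(unique(beh$subject_id)),
               sprintf("sub%02d", 1:4))
})

test_that("engine calibration: Gaussian null behavior rejects at ~q", {
  # isolates the regression + BH machinery from the skewed binomial score
  # distribution: with Gaussian behavior the familywise rejection rate over
  # cohorts should be near the FDR level
  co <- generate_cohort(cohort_config(seed = 7, effect_beta = 0))
  masks <- lapply(co$subjects, function(s)
    if (s$side == "left") flip_hemisphere(s$lesion) else s$lesion)
  inc <- build_inclusion_mask(overlap_map(masks), 3)
  lm_ <- dtlvc_weights(lesion_matrix(masks, inc))
  withr::with_seed(101, {
    any_rej <- vapply(1:150, function(i) {
      y <- demean(rnorm(length(masks)))
      any(fdr_correct(voxelwise_regression(lm_, y)$p)$significant)
    }, TRUE)
  })
  expect_lte(mean(any_rej), 0.10)
})
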