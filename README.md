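# lesionmapr

Voxel-based lesion–symptom mapping of residual vision after occipital
stroke.

Damage to the primary visual cortex (V1) or its afferents causes homonymous
hemianopia — blindness in one half of the visual field. Many patients
nevertheless retain *residual vision*: above-chance detection of stimuli
presented inside the blind field. `lesionmapr` implements the full analysis
chain used to ask *which* damaged structures abolish that residual ability:

- **Consensus lesion masking.** Three or four raters independently delineate
  each lesion; their binary masks are summed and thresholded at 1.9, keeping
  exactly the voxels marked by at least two raters.
- **Atlas ROI damage.** Probabilistic atlas volumes for V1, V4 and hMT+/V5
  are thresholded (conventionally 50/30/10%, reflecting each area's
  anatomical variability) and the fraction of each area overlapped by the
  consensus lesion is tabulated per subject.
- **2AFC behavioral scoring.** Two-alternative forced-choice detection
  (chance = 50%) is scored per task with an exact one-sided cumulative
  binomial test against Binomial(n, ½); with 20 trials, proportions ≥ 75%
  or ≤ 25% differ from chance at α = 0.05. Non-significant scores below 50%
  are conservatively floored at 50% before any correlation.
- **VLSM.** For the cohort (bilateral cases excluded, left-sided lesions
  mirrored to the right hemisphere), every voxel lesioned in ≥ 3 subjects
  enters a mass-univariate analysis. Each subject's binary lesion vector
  *l* is weighted by direct total lesion volume control (dTLVC),
  *l* → *l*/√V, giving every subject unit lesion norm so stroke severity
  alone cannot drive the statistic. At each voxel, demeaned percent correct
  is regressed on the weighted damage score (OLS; one-sided slope *t*-test,
  damage → worse performance), p-values are Benjamini–Hochberg corrected at
  q = 0.05, and surviving voxels are grouped into 26-connected clusters.
- **Group statistics.** Spearman rank correlations with Bonferroni-adjusted
  alphas (0.05/3 = 0.0167 across tasks; 0.05/9 = 0.006 across the
  area × task grid), Friedman tests across atlas thresholds, a paired
  Wilcoxon test (faces vs places), and a linear-vs-quadratic extra
  sum-of-squares F-test, F = ((SS₁ − SS₂)/1)/(SS₂/(n − 3)).
- **Synthetic cohorts.** Because patient data cannot be redistributed, a
  generator produces full cohorts — multifocal posterior lesions, noisy
  rater delineations, and behavior driven by a planted deficit
  p\* = clamp(baseline − β·damage, 50, 100) plus binomial trial noise — so
  the whole pipeline is testable end to end with known ground truth.

## Worked example

```r
library(lesionmapr)

cfg    <- cohort_config(seed = 1)     # 39 subjects, planted effect beta = 45
cohort <- generate_cohort(cfg)
#> <synthetic_cohort> n=39 (left=20, right=19), seed 1

# score one subject's contrast task (high contrasts only, 20 trials)
s <- cohort$subjects[[2]]
score_task(s$behavior[s$behavior$task == "contrast", ])
#> $n_correct 19; $percent_raw 95; $p_binomial 2e-05
#> $category "above_chance"; $percent_adjusted 95

res <- run_vlsm(cohort$subjects, task = "contrast")
#> <vlsm_result> task=contrast, n=39 subjects (0 excluded bilateral)
#>   included voxels: 9182 (73.5 cm3); significant: 2100 in 21 cluster(s)

head(res$clusters, 3)
#>   cluster_id voxel_count volume_mm3 peak_i peak_j peak_k
#> 1          1        2070      16560     24     13     14
#> 2          2           6         48     25     18     24
#> 3          3           3         24     18     18     31

labs    <- attr(res$clusters, "labels")
largest <- mask_volume(array(as.integer(labs == 1), dim(labs)),
                       res$inclusion_mask$grid)
dice(largest, cohort$truth$critical_mask)
#> 0.355
```

The 73.5 cm³ inclusion volume is the tissue damaged in at least three of
the 39 subjects; the dominant cluster (2070 voxels, 16.6 cm³, peak at voxel
24/13/14) sits on the planted critical region — its Dice overlap of 0.355
with the 711-voxel ground-truth ellipsoid reflects the well-known spatial
smear of mass-univariate VLSM, in which voxels whose damage co-occurs with
critical damage also reach significance.

A disk-based workflow (NIfTI masks + behavior TSV in, maps/tables out) is
available through `run_full_analysis()` or the thin CLI in
`inst/cli/lesionmapr` (subcommands `simulate`, `score`, `vlsm`, `full`).

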