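---
title: "Mapping residual vision: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping residual vision: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmapr)
```

## The analysis problem

After a posterior-circulation stroke that destroys V1 or its inputs,
patients lose conscious vision in the contralateral hemifield, yet some
retain residual detection ability inside the blind field. The analytic
question is anatomical: which damaged voxels, beyond V1 itself, predict the
*loss* of that residual ability? `lesionmapr` answers it with a
mass-univariate voxel-based lesion–symptom mapping (VLSM) pipeline plus the
supporting machinery (consensus masking, ROI damage, behavioral scoring,
cohort statistics) needed to run the analysis end to end.

All volumes must live on one shared template grid. Registration to that
grid is deliberately out of scope: it is the job of established nonlinear
registration tools, and this package validates grid identity instead of
resampling. The first voxel axis is the left–right axis by convention;
`flip_hemisphere()` mirrors about the voxel midline ((Nx−1)/2), which
assumes a grid symmetric about the mid-sagittal plane — the mirror is an
exact involution and preserves voxel counts.

## Consensus masking

Independent raters (3 or 4) each produce a binary lesion mask. The masks
are summed voxelwise and thresholded at 1.9, so a voxel survives exactly
when at least two raters marked it. The threshold applies unchanged with
three raters — the rule is "at least two", not "half". Masks are binarized
on load at > 0.5 so that masks that passed through trilinear interpolation
remain binary.

## ROI damage

Probabilistic atlas volumes carry, per voxel, the percentage of reference
brains in which the voxel belonged to the area. Thresholding is inclusive
(≥), so masks at rising thresholds are nested. The conventional thresholds
encode anatomical variability: V1 is consistent across brains (50%), V4
intermediate (30%), hMT+/V5 highly variable (10%). Damage is the fraction
of thresholded ROI voxels overlapped by the consensus lesion; it is
undefined (an error, never a silent 0) for an empty ROI. Atlases arriving
on a 0–1 scale are rescaled to percent with a warning. When the cohort is
hemisphere-normalized, left-sided lesions are mirrored and right-hemisphere
ROIs serve all subjects.

## Behavioral scoring

All tasks are two-alternative forced choice, so chance is 50%. Scoring per
task follows the study design:

* **contrast** — only the two high-contrast conditions (50, 100%) are
  pooled (20 trials at the 10-trials-per-condition default); low contrasts
  are near chance for nearly all patients and would dilute the score;
* **motion** — all four speeds pooled;
* **faceplace** — faces and places pooled (the package also provides the
  paired Wilcoxon test used to justify pooling).

The pooled count is tested against Binomial(n, ½) with an exact one-sided
tail in the direction of the observation, α = 0.05 per direction. With
n = 20 this makes ≥ 75% the smallest significant above-chance proportion
and ≤ 25% the largest significant below-chance one; `binomial_chance_test()`
is verified against full pmf enumeration for every n ≤ 64. Scores below 50%
that are *not* significantly below chance are floored at 50
(`adjust_floor()`): sub-chance noise otherwise manufactures spurious
damage–behavior correlations. Significant below-chance scores are retained
as observed. A score of exactly 50% uses the upper tail and is at chance
for any n ≥ 2.

## The VLSM engine

For subjects with a unilateral lesion (bilateral cases are excluded and
reported, never dropped silently), left-sided masks are mirrored so the
whole cohort's damage sits in one hemisphere. Voxels lesioned in fewer than
`min_subjects = 3` subjects are excluded — below that there is no within-
voxel contrast worth testing.

Each subject's binary lesion vector is weighted by **direct total lesion
volume control**: division by √V, with V the subject's total lesion voxel
count over the *full* grid (not just included voxels). Every subject's
full-grid lesion vector then has unit Euclidean norm, so overall lesion
size cannot by itself drive the voxel statistic. The weighting changes
statistic values but never which voxels are analyzed.

At each included voxel the demeaned, floor-adjusted percent correct is
regressed on the weighted damage score by ordinary least squares. The
statistic is the slope *t* on n − 2 df; the default test is one-sided
(damage predicts *worse* performance), with a two-sided option. Degenerate
voxels — zero predictor variance after weighting, e.g. all subjects
lesioned — are flagged and assigned p = 1, never dropped. A zero residual
with a nonzero slope yields t = ±∞ (p = 0 or 1); a zero slope with zero
residual yields t = 0. The vectorized engine is tested against a per-voxel
`lm()` loop to 10⁻¹⁰.

Multiplicity is handled by Benjamini–Hochberg step-up FDR at q = 0.05 over
the included voxels; the q-map holds the standard step-up adjusted values
and a voxel is significant exactly when its q ≤ q-level. Significant voxels
are grouped into clusters under 26-connectivity (6 available), sorted by
size, with the peak taken at the most extreme statistic.

## The synthetic cohort generator

No patient data ship with the package; the generator defines the study
conditions every test runs under.

* Grid 32 × 38 × 32 at 2 mm isotropic. The posterior half of one hemisphere
  (~9,700 voxels, margin of one voxel from the midline so rater jitter
  cannot cross it) stands in for an occipital lobe.
* 39 subjects; a lesion is left-sided with probability 21/39.
* Lesion sizes are log-uniform over 100–6,000 voxels (≈ 1–62% of the
  synthetic occipital lobe), matching the wide size range seen in
  hemianopic cohorts. A lesion is the target number of voxels closest, in
  scaled ellipsoid distance, to 1–3 independently placed ellipsoid foci —
  multifocal posterior damage with exactly controlled size.
* Four raters each return the true mask, dilated or eroded by one voxel
  with probability 0.3 each, plus 5% of boundary-shell voxels flipped. At
  these defaults the 2-of-4 consensus recovers the truth at Dice ≥ 0.8.
* Behavior follows a planted deficit model:
  p\* = clamp(baseline − β·d + σz, 50, 100)/100 with baseline 95%,
  β = 45 (full critical-region damage drives performance to chance),
  σ = 3 as a Gaussian subject effect, and per-condition correct counts
  drawn Binomial(10, p\*). d is the damage fraction of the critical region
  computed after mirroring, so left-sided lesions are symmetric in effect.
* The critical region is an ellipsoid (radii 5 × 7 × 5 voxels, ~711 voxels
  ≈ 5.7 cm³) in the right posterior white matter of the grid — an
  optic-radiation-scale target, deliberately *not* V1, mirroring the
  finding that V1 damage extent does not itself predict residual vision.
  The scale is a design calibration: mass-univariate VLSM under these
  cohort conditions has a spatial grain of hundreds to thousands of voxels
  (lesion size confounds critical damage, and dTLVC reweights but cannot
  remove that coupling), so a planted target far below that grain would
  make overlap scores uninformative about whether localization works.

Everything is reproducible from one integer seed via per-subject,
per-stage derived seeds; generation never perturbs the caller's RNG state.

What the generator does **not** emulate: anatomically shaped vascular
territories, perimetric field maps, rater biases that correlate across
raters, lapse rates, and partial-volume effects. Passing recovery tests
therefore demonstrates that the statistical machinery localizes a planted
effect under controlled conditions — not that it would do so at the same
fidelity on clinical data.

## Numerical and design notes

* Spearman's ρ is the Pearson correlation of mid-ranks; p is an exact
  permutation enumeration for n ≤ 9 and the t approximation otherwise.
  Fisher-z intervals are attached but approximate for ranks.
* Friedman and Wilcoxon tests delegate to the standard R implementations,
  with two guards: rank-identical Friedman input returns statistic 0
  exactly (the tie-corrected form is 0/0 there), and an all-tied paired
  Wilcoxon returns an explicit "no informative pairs" result.
* The linear-vs-quadratic comparison uses
  F = ((SS₁ − SS₂)/1)/(SS₂/(n − 3)), preferring the quadratic at p < 0.05.
* Bonferroni alphas are reported rounded as printed in the field
  (0.05/3 → 0.0167 at 4 dp, 0.05/9 → 0.006 at 3 dp).
* Cluster connectivity defaults to 26 (the common neuroimaging choice; the
  pipeline does not depend on it for inference, only for reporting).
* Tables join strictly on `subject_id`: a subject present in one table and
  missing from another is an error, not a filter.

Problem sizes in the shipped tests were chosen to exercise every code path
at desk scale: exhaustive enumerations where the domain is finite (2⁴ rater
patterns, all binomial counts for n ≤ 64), 6³-grid regression oracles with
20 subjects, 2,000-replicate FDR null simulations at m = 500, and
full-default cohorts (n = 39) for recovery, specificity and monotonicity.

## Known limitations

* **Parametric fragility at the ceiling.** 2AFC percent-correct scores near
  a 95% baseline are strongly left-skewed, and the one-sided lower-tail
  OLS t-test inherits that skew: a single low-scoring subject produces
  extreme negative slopes at the voxels only they and few others carry.
  Under a no-effect simulation the familywise rate of finding *any*
  significant voxel is ≈ 15% rather than the nominal ≈ 5%, even though the
  identical engine is correctly calibrated under Gaussian behavior (≈ 4%;
  both measurements are in the test suite). Benjamini–Hochberg cannot
  repair invalid per-voxel p-values. Practical mitigations — rank-based
  voxel statistics or permutation-calibrated p-values — are deliberately
  out of scope here, where the parametric regression is the reference
  method being implemented; users analyzing near-ceiling scores should
  treat isolated small clusters with caution.
* Univariate VLSM localizes with substantial spatial smear; the recovery
  Dice of ~0.3–0.5 on synthetic cohorts quantifies that smear rather than
  a defect of the implementation.
* ROI damage is computed on the common grid; analyses that inverse-warp
  ROIs to native space will differ by interpolation.
* The flip convention requires the left–right axis first and a midline-
  symmetric grid; no automatic reorientation is attempted.
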