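Package: lesionmapr
Title: Voxel-Based Lesion-Symptom Mapping of Residual Vision After Occipital Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end lesion-analysis pipeline for localizing residual
    visual function in homonymous hemianopia. Provides multi-rater consensus
    lesion masking on a common template grid, probabilistic-atlas ROI damage
    quantification at configurable thresholds, exact-binomial scoring of
    two-alternative forced-choice detection performance with a conservative
    floor-at-chance adjustment, and mass-univariate voxel-based
    lesion-symptom mapping (VLSM) with direct total lesion volume control
    (dTLVC), Benjamini-Hochberg FDR correction, and 26-connected cluster
    extraction. Includes cohort-level nonparametric statistics (Spearman
    correlations with Bonferroni control, Friedman and Wilcoxon tests,
    linear-versus-quadratic fit comparison) and a synthetic-cohort generator
    with planted lesion-deficit effects for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
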