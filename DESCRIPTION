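Package: wmconsist
Title: Test-Retest Consistency of Voxel-Wise White-Matter Measure Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Evaluates the longitudinal consistency of voxel-wise white-matter
    measure maps collected over repeated MRI sessions. Implements the image
    intraclass correlation coefficient (I2C2) as a one-way random-effects,
    absolute-agreement trace-ratio estimator on vectorized images, with
    densification of measure values over unions of imperfectly overlapping
    bundle masks; within- and between-subject coefficients of variation;
    subject-level nonparametric bootstrap with bias-corrected and accelerated
    (BCa) confidence intervals and p-values; along-bundle section profiles,
    fiber-population compartments from number-of-fiber-orientations maps, and
    volume-based quality control; pairwise Dice and density-map correlation for
    bundle-segmentation reproducibility; and per-session Pearson correlation
    matrices between measures averaged across sessions. A synthetic cohort
    generator with known between-/within-subject variance components supports
    validation of every estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
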