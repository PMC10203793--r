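# wmconsist

Test–retest consistency of voxel-wise white-matter measure maps.

Longitudinal MRI studies and clinical trials need to know how reliably a
white-matter measure (FA, MD, AFD, NODDI fractions, magnetization-transfer
ratios, …) can be re-measured in the same subjects across sessions.
`wmconsist` quantifies that consistency for bundle-shaped regions of
interest, the way scan–rescan studies report it:

- **Reliability** — the image intraclass correlation coefficient (I2C2), a
  one-way random-effects, absolute-agreement ICC generalized to vectorized
  images. For records `W_ij` (subject *i*, session *j*), per-subject mean
  images `W̄_i`, grand mean `W̄`, N records and I subjects, the
  method-of-moments trace-ratio estimator is

  ```
  λ̂ = 1 − T_w / T_t,
  T_w = Σ_ij ‖W_ij − W̄_i‖² / (N − I),   T_t = Σ_ij ‖W_ij − W̄‖² / (N − 1),
  ```

  with norms summed over the voxels of the analysis mask. On single-voxel
  images this reduces to the classical scalar one-way ICC.
- **Variability** — within-subject CV (CVw: the CV of each subject's session
  values, averaged across subjects) and between-subject CV (CVb: the CV of
  the per-subject session averages), both in percent.
- **Inference** — subject-level nonparametric bootstrap with accelerated
  bias-corrected (BCa) percentile intervals and p-values by interval
  inversion.
- **Masks as the study built them** — per-session bundle masks eroded by one
  voxel into a "safe mask", left/right merging, ten equidistant along-bundle
  sections, single- vs multi-fiber compartments from number-of-fiber-
  orientations (NuFO) maps at thresholds 1 and ≥ 2, volume-based QC (mean
  volume ≥ 1000 voxels per section, ≥ 400 per compartment), and invalidation
  of ISOvf values below 0.045.
- **Densification** — voxel-level analyses run over the union of all record
  masks; a voxel missing from one record is imputed with the mean of the
  records that observe it (same subject's sessions first, cohort otherwise).
- **Segmentation reproducibility** — pairwise Dice and density-map Pearson
  correlation over all session pairs per subject.
- **Measure correlation** — per-session Pearson matrices between bundle-mean
  measures across subjects, averaged over sessions.

Because scan–rescan MRI cohorts are rarely shareable, the package ships a
synthetic cohort generator (`simulate_cohort()`) with known
between-/within-subject variance components, so that every estimator is
validated by parameter recovery: under the generator's hierarchical model
the population I2C2 is `σ_b² / (σ_b² + σ_w²)` exactly.

## Worked example

```r
library(wmconsist)

params <- sim_params(n_subjects = 10, n_sessions = 3, radius = 4, length = 20,
                     n_sections = 4, mask_jitter = 0.05,
                     measures = list(measure_spec("fa", 0.5, 0.05, 0.02, 0.05, 2)),
                     seed = 42)
cohort <- simulate_cohort(params)
cohort
#> <cohort_dataset> 10 subjects, 30 records, grid 13x13x24@1mm
#>   measures: fa

analyze_cell(cohort, "fa", B = 2000, seed = 42)
#> fa | whole bundle | average
#>   I2C2 0.814 [0.507, 0.928], p = 0.001
#>   CVw 3.03%, CVb 7.69% (10 subjects, 30 records, 671 voxels, 25.1% imputed)

pairwise_reproducibility(cohort)$summary
#>      metric      mean       min       max
#> 1      dice 0.9505945 0.9462711 0.9574013
#> 2 density_r 0.9024282 0.8880112 0.9206135
```

The simulated measure has `σ_b = 0.05`, `σ_w = 0.02`, hence a population
I2C2 of `0.05² / (0.05² + 0.02²) ≈ 0.862`; the estimate 0.814 with BCa
interval [0.51, 0.93] recovers it within sampling error of a 10 × 3 design.
CVw ≈ 3% says repeated sessions of one subject differ by a few percent of
the mean; CVb ≈ 8% reflects the simulated cohort heterogeneity; mean Dice
0.95 quantifies the session-to-session mask agreement induced by the 5%
boundary jitter.

The full pipeline — QC, every (measure × whole/section × compartment) cell,
reproducibility and correlation tables written as CSV/JSON —

```r
res <- run_pipeline(pipeline_config(params = sim_params(), seed = 1,
                                    out_dir = "out"))
```

A thin command-line wrapper with `simulate`, `analyze` and `report`
subcommands lives at `inst/scripts/wmconsist.R`.

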