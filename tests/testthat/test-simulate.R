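test_that("bundle geometry partitions the tube into equal sections with remainder at the end", {
  # even split: 100 slices over 10 sections -> 10 slices each
  p <- sim_params(radius = 2, length = 100, n_sections = 10,
                  grid = voxel_grid(c(7, 7, 104)))
  g <- generate_bundle_geometry(p)
  slice_counts <- tabulate(g$labels[g$labels > 0], 10)
  per_slice <- sum(g$mask[, , dim(g$mask)[3] %/% 2])
  expect_equal(slice_counts, rep(10L * per_slice, 10))

  # remainder rule: 103 slices -> sections 1-9 span 10 slices, section 10 spans 13
  p2 <- sim_params(radius = 2, length = 103, n_sections = 10,
                   grid = voxel_grid(c(7, 7, 106)))
  g2 <- generate_bundle_geometry(p2)
  counts2 <- tabulate(g2$labels[g2$labels > 0], 10) / per_slice
  expect_equal(counts2, c(rep(10, 9), 13))

  # degenerate partition: a single section labels the whole mask with 1
  p3 <- sim_params(radius = 2, length = 9, n_sections = 1,
                   grid = voxel_grid(c(7, 7, 12)))
  g3 <- generate_bundle_geometry(p3)
  expect_identical(g3$labels > 0, g3$mask)
  expect_setequal(unique(g3$labels[g3$mask]), 1L)
})

test_that("geometry errors name the offending grid dimension", {
  p <- sim_params(radius = 4, length = 10, n_sections = 2,
                  grid = voxel_grid(c(5, 20, 20)))
  expect_error(generate_bundle_geometry(p), "x extent")
  p2 <- sim_params(radius = 2, length = 30, n_sections = 2,
                   grid = voxel_grid(c(20, 20, 10)))
  expect_error(generate_bundle_geometry(p2), "z extent")
})

test_that("NuFO maps honour the multi-fiber fraction", {
  mask <- array(TRUE, c(25, 20, 20))  # 10,000 voxels
  all_single <- generate_nufo_map(mask, 0, seed = 1)
  expect_true(all(all_single[mask] == 1L))
  all_multi <- generate_nufo_map(mask, 1, seed = 1)
  expect_true(all(all_multi[mask] >= 2L))
  expect_true(all(all_multi[mask] <= 3L))
  # binomial concentration at n = 10,000
  nufo <- generate_nufo_map(mask, 0.8, seed = 42)
  frac_multi <- mean(nufo[mask] >= 2L)
  expect_gte(frac_multi, 0.78)
  expect_lte(frac_multi, 0.82)
  # zero outside the mask
  half <- mask_from_idx(c(4, 4, 4), 1:10)
  expect_true(all(generate_nufo_map(half, 0.5, seed = 3)[!half] == 0L))
})

test_that("simulated cohorts are bit-identical given identical parameters", {
  p <- one_measure_params(seed = 7, n_subjects = 3, n_sessions = 2,
                          mask_jitter = 0.2, sigma_v = 0.3, fwhm = 2)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$records, b$records)
  # and a different seed changes the data
  c <- simulate_cohort(one_measure_params(seed = 8, n_subjects = 3,
                                          n_sessions = 2, mask_jitter = 0.2,
                                          sigma_v = 0.3, fwhm = 2))
  expect_false(identical(a$records, c$records))
})

test_that("zero variance components produce constant in-mask values equal to mu", {
  p <- one_measure_params(seed = 3, n_subjects = 3, n_sessions = 2,
                          mu = 0.5, sigma_b = 0, sigma_w = 0, sigma_v = 0,
                          mask_jitter = 0)
  co <- simulate_cohort(p)
  for (r in co$records) {
    expect_true(all(r$measures$m[r$mask] == 0.5))
    expect_true(all(is.nan(r$measures$m[!r$mask])))
  }
})

test_that("unjittered masks are identical across records and jittered ones are not", {
  p <- one_measure_params(seed = 11, n_subjects = 2, n_sessions = 3)
  co <- simulate_cohort(p)
  masks <- lapply(co$records, function(r) r$mask)
  for (m in masks[-1]) expect_identical(masks[[1]], m)

  pj <- one_measure_params(seed = 11, n_subjects = 2, n_sessions = 3,
                           mask_jitter = 0.3)
  coj <- simulate_cohort(pj)
  masksj <- lapply(coj$records, function(r) r$mask)
  expect_false(identical(masksj[[1]], masksj[[2]]))
})

test_that("unbalanced designs honour per-subject session counts", {
  p <- sim_params(n_subjects = 3, n_sessions = c(1, 2, 4), radius = 2,
                  length = 8, n_sections = 2,
                  measures = list(measure_spec("m", 1, 0.1, 0.1)), seed = 5)
  co <- simulate_cohort(p)
  counts <- table(record_subjects_vec(co))
  expect_equal(as.integer(counts), c(1L, 2L, 4L))
})

test_that("measure_spec rejects non-positive means", {
  expect_error(measure_spec("m", 0, 1, 1), "positive")
  expect_error(measure_spec("m", -2, 1, 1), "positive")
})

test_that("cohorts round-trip through the NIfTI directory layout", {
  p <- one_measure_params(seed = 9, n_subjects = 2, n_sessions = 2,
                          mask_jitter = 0.2, sigma_v = 0.4, fwhm = 2,
                          n_sections = 3, length = 12)
  co <- simulate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "sub-01", "ses-02", "m.nii.gz")))
  back <- read_cohort(dir)
  expect_equal(names(back$records), names(co$records))
  for (nm in names(co$records)) {
    expect_identical(back$records[[nm]]$mask, co$records[[nm]]$mask)
    expect_equal(back$records[[nm]]$measures$m, co$records[[nm]]$measures$m)
    expect_equal(back$records[[nm]]$sections, co$records[[nm]]$sections)
  }
  expect_equal(back$truth$n_subjects, 2L)
})
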