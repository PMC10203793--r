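test_that("density binarization uses a strict threshold and drops NaN", {
  d <- array(0, c(3, 3, 3))
  expect_equal(mask_volume(binarize_density(d)), 0L)

  d[c(1, 5, 9, 11, 14, 20, 27)] <- c(0.2, 1, 3, 0.5, 2, 0.1, 5)
  expect_equal(mask_volume(binarize_density(d)), 7L)
  # threshold equal to the max leaves nothing (strict inequality)
  expect_equal(mask_volume(binarize_density(d, 5)), 0L)
  d[2] <- NaN
  expect_equal(mask_volume(binarize_density(d)), 7L)
  expect_error(binarize_density(d, -1), "non-negative")
})

test_that("erosion matches a brute-force 6-connectivity oracle", {
  # 3x3x3 solid cube -> single centre voxel
  cube <- array(TRUE, c(3, 3, 3))
  er <- erode_mask(cube, 1)
  expect_equal(which(er), 14L)
  # single voxel erodes away
  single <- mask_from_idx(c(3, 3, 3), 14)
  expect_equal(mask_volume(erode_mask(single, 1)), 0L)
  # random masks against the naive oracle
  set.seed(42)
  for (k in 1:5) {
    m <- array(runif(5 * 4 * 6) < 0.6, c(5, 4, 6))
    expect_identical(erode_mask(m, 1), naive_erode(m))
  }
})

test_that("erosion composes: k then m iterations equals k + m", {
  set.seed(7)
  m <- dilate_mask(mask_from_idx(c(9, 9, 9), 365), 3)  # octahedron
  expect_identical(erode_mask(erode_mask(m, 1), 2), erode_mask(m, 3))
  # and the result is always a subset of the input
  r <- array(runif(7^3) < 0.7, c(7, 7, 7))
  expect_true(all(which(erode_mask(r, 1)) %in% which(r)))
})

test_that("merging left/right masks is a voxelwise union", {
  left <- mask_from_idx(c(4, 4, 4), 1:10)
  right <- mask_from_idx(c(4, 4, 4), 20:31)
  expect_equal(mask_volume(merge_lr(left, right)), 22L)
  expect_equal(mask_volume(merge_lr(left, left)), 10L)
  overlap <- mask_from_idx(c(4, 4, 4), 8:19)  # 3 voxels shared with left
  expect_equal(mask_volume(merge_lr(left, overlap)), 19L)
  expect_error(merge_lr(left, array(TRUE, c(3, 3, 3))), "grid mismatch")
})

test_that("section splitting intersects labels with the safe mask", {
  p <- sim_params(radius = 2, length = 12, n_sections = 3,
                  grid = voxel_grid(c(9, 9, 16)),
                  measures = list(measure_spec("m", 1, 0.1, 0.1)))
  g <- generate_bundle_geometry(p)
  # labels cover the mask: sections partition it
  secs <- split_sections(g$mask, g$labels)
  expect_equal(length(secs), 3L)
  expect_identical(Reduce(`|`, secs), g$mask)
  expect_equal(sum(vapply(secs, mask_volume, 0L)), mask_volume(g$mask))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(mask_volume(secs[[i]] & secs[[j]]), 0L)
  }
  # an empty safe mask gives empty sections
  empty <- array(FALSE, dim(g$mask))
  expect_true(all(vapply(split_sections(empty, g$labels), mask_volume, 0L) == 0L))
  # removing 5 voxels of section 2 from the safe mask shrinks it by exactly 5
  safe <- g$mask
  safe[which(g$labels == 2L)[1:5]] <- FALSE
  secs2 <- split_sections(safe, g$labels)
  expect_equal(mask_volume(secs2[[2]]), mask_volume(secs[[2]]) - 5L)
})

test_that("fiber-population compartments are disjoint and conserve volume", {
  mask <- mask_from_idx(c(4, 4, 4), 1:10)
  nufo <- array(0L, c(4, 4, 4))
  nufo[1:4] <- 1L
  nufo[5:10] <- c(2L, 3L, 2L, 2L, 3L, 2L)
  cp <- compartmentalize(mask, nufo)
  expect_equal(mask_volume(cp$single), 4L)
  expect_equal(mask_volume(cp$multi), 6L)
  expect_equal(mask_volume(cp$single & cp$multi), 0L)

  # all-single leaves multi empty; nufo == 0 voxels drop out of both
  nufo1 <- array(0L, c(4, 4, 4)); nufo1[1:10] <- 1L
  expect_equal(mask_volume(compartmentalize(mask, nufo1)$multi), 0L)
  nufo0 <- array(0L, c(4, 4, 4))
  cp0 <- compartmentalize(mask, nufo0)
  expect_equal(mask_volume(cp0$single) + mask_volume(cp0$multi), 0L)

  # conservation on random data
  set.seed(1)
  nufor <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  cpr <- compartmentalize(mask, nufor)
  expect_equal(mask_volume(cpr$single) + mask_volume(cpr$multi) +
                 mask_volume(mask & (nufor == 0L)),
               mask_volume(mask))
})

test_that("volume QC excludes strictly below the scope threshold", {
  res <- apply_volume_qc(c(a = 999, b = 1000, c = 0), "section")
  expect_equal(res$excluded, c("a", "c"))
  expect_equal(res$kept, "b")
  res2 <- apply_volume_qc(c(x = 400, y = 399.9), "compartment")
  expect_equal(res2$kept, "x")
  expect_equal(res2$excluded, "y")
  expect_error(apply_volume_qc(c(a = 10), "bundle"), "unknown scope")
  # all-zero volumes exclude everything
  res3 <- apply_volume_qc(c(u = 0, v = 0), "compartment")
  expect_equal(length(res3$kept), 0L)
  expect_s3_class(res3$log, "data.frame")
})

test_that("ISOvf thresholding invalidates (not clips) sub-cutoff voxels", {
  v <- c(0.01, 0.05, 0.10)
  out <- threshold_isovf(v, 0.045)
  expect_true(is.nan(out[1]))
  expect_equal(out[2:3], c(0.05, 0.10))
  # cutoff 0 is a no-op
  expect_identical(threshold_isovf(v, 0), v)
  # all below cutoff -> all invalid
  expect_true(all(is.nan(threshold_isovf(c(0.01, 0.02), 0.045))))
  expect_error(threshold_isovf(v, -0.1), "non-negative")
})
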