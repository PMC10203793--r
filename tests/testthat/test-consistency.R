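test_that("densification is a no-op for fully overlapping masks", {
  set.seed(1)
  dimg <- c(4, 4, 4)
  mask <- mask_from_idx(dimg, 1:20)
  maps <- lapply(1:6, function(i) {
    a <- array(NaN, dimg)
    a[1:20] <- rnorm(20, mean = 5)
    a
  })
  subject <- rep(c("a", "b", "c"), each = 2)
  rm <- union_and_densify(maps, rep(list(mask), 6), subject)
  direct <- do.call(rbind, lapply(maps, function(a) a[1:20]))
  expect_identical(rm$values, direct)
  expect_true(all(rm$available))
})

test_that("an unobserved voxel is imputed with the mean of the observing records", {
  dimg <- c(3, 3, 1)
  base <- mask_from_idx(dimg, 1:5)
  # records of 5 distinct subjects; the 5th record misses voxel 3
  masks <- c(rep(list(base), 4), list(mask_from_idx(dimg, c(1, 2, 4, 5))))
  maps <- lapply(1:5, function(i) {
    a <- array(NaN, dimg)
    a[1:5] <- i
    if (i == 5) a[3] <- NaN
    a
  })
  maps[[1]][3] <- 1; maps[[2]][3] <- 2; maps[[3]][3] <- 3; maps[[4]][3] <- 4
  rm <- union_and_densify(maps, masks, subject = letters[1:5])
  col3 <- which(rm$voxel_index == 3)
  expect_equal(rm$values[5, col3], mean(c(1, 2, 3, 4)))
  expect_false(rm$available[5, col3])
})

test_that("imputation prefers the same subject's other sessions", {
  dimg <- c(2, 2, 1)
  full <- array(TRUE, dimg)
  part <- mask_from_idx(dimg, c(1, 2, 3))
  masks <- list(full, part, full, full)
  vals <- list(c(10, 10, 10, 12), c(10, 10, 10, NA),
               c(1, 1, 1, 2), c(1, 1, 1, 4))
  maps <- lapply(vals, function(v) array(v, dimg))
  # record 2 (subject a, session 2) misses voxel 4; subject a's other session
  # observes it with value 12, so the fill is 12, not the cohort mean 6.
  rm <- union_and_densify(maps, masks, subject = c("a", "a", "b", "b"))
  expect_equal(rm$values[2, 4], 12)
})

test_that("voxels observed nowhere are dropped and empty unions error", {
  dimg <- c(2, 2, 1)
  m <- mask_from_idx(dimg, 1:2)
  a <- array(c(1, NaN, NaN, NaN), dimg)  # voxel 2 in-mask but invalid everywhere
  rm <- suppressWarnings(union_and_densify(list(a, a), list(m, m), c("a", "b")))
  expect_equal(ncol(rm$values), 1L)
  empty <- array(FALSE, dimg)
  expect_error(union_and_densify(list(a, a), list(empty, empty), c("a", "b")),
               "no analyzable voxels")
})

test_that("densifying disjoint masks warns about the imputation fraction", {
  dimg <- c(3, 2, 1)
  masks <- lapply(list(1:2, 3:4, 5:6), function(ix) mask_from_idx(dimg, ix))
  maps <- lapply(masks, function(m) {
    a <- array(NaN, dimg)
    a[m] <- c(1, 2)
    a
  })
  # each union voxel observed in 1 of 3 records -> 2/3 imputed
  expect_warning(union_and_densify(maps, masks, c("a", "b", "c")), "> 50%")
})

test_that("i2c2 equals 1 when subjects are internally identical but differ", {
  X <- rbind(c(1, 2), c(1, 2), c(5, 7), c(5, 7))
  expect_equal(i2c2(X, subject = c("a", "a", "b", "b")), 1)
  # nested scalar case from two subjects
  expect_equal(i2c2(c(1, 1, 3, 3), subject = c("a", "a", "b", "b")), 1)
})

test_that("i2c2 on single-voxel images equals the one-way ANOVA ICC oracle", {
  set.seed(202)
  for (k in 1:25) {
    I <- sample(3:10, 1)
    J <- sample(2:6, 1)
    y <- rnorm(I * J, mean = rep(rnorm(I, sd = runif(1, 0, 2)), each = J))
    subj <- rep(sprintf("s%02d", seq_len(I)), each = J)
    expect_equal(i2c2(y, subject = subj), anova_icc(y, subj), tolerance = 1e-12)
  }
})

test_that("i2c2 warns and returns 1 when all records are identical", {
  X <- matrix(1, 4, 3)
  expect_warning(out <- i2c2(X, subject = c("a", "a", "b", "b")), "identical")
  expect_equal(out, 1)
})

test_that("i2c2 is invariant to adding a constant image and bounded by 1", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5) + rep(rnorm(4, sd = 2), each = 2)
  subj <- rep(letters[1:4], each = 2)
  base <- i2c2(X, subject = subj)
  shift <- matrix(rnorm(5, sd = 10), 8, 5, byrow = TRUE)  # same image each record
  expect_equal(i2c2(X + shift, subject = subj), base, tolerance = 1e-10)
  expect_lte(base, 1)
})

test_that("estimated I2C2 decreases as within-subject noise grows", {
  mean_est <- vapply(c(0.5, 1, 2), function(sw) {
    mean(vapply(1:30, function(s) {
      co <- simulate_cohort(one_measure_params(seed = 4000 + s,
                                               sigma_b = 1, sigma_w = sw,
                                               n_subjects = 10, n_sessions = 3))
      cohort_i2c2(co)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_est) < 0))
})

test_that("coefficients of variation match hand computations", {
  # sessions [9, 10, 11]: sd = 1, mean = 10 -> CV_i = 10%
  expect_equal(cv_within(c(9, 10, 11), rep("a", 3)), 10)
  # two subjects with CVs 4% and 6% average to 5%
  # (two sessions x +/- d have mean x and sd d * sqrt(2))
  a <- 100 + c(-1, 1) * 4 / sqrt(2) * 100 / 100   # CV 4%
  b <- 50 + c(-1, 1) * 0.06 * 50 / sqrt(2)        # CV 6%
  expect_equal(cv_within(c(a, b), c("a", "a", "b", "b")), 5, tolerance = 1e-12)
  # identical sessions -> CVw = 0
  expect_equal(cv_within(c(3, 3, 5, 5), c("a", "a", "b", "b")), 0)
  # subject means {1, 2} -> CVb = 100 * sd/mean = 47.1404...
  expect_equal(cv_between(c(1, 2), c("a", "b")), 100 * sqrt(0.5) / 1.5,
               tolerance = 1e-12)
  expect_equal(cv_between(c(4, 4, 4), c("a", "b", "c")), 0)
})

test_that("CV preconditions are enforced", {
  expect_error(cv_within(c(-1, 1, 2, 3), c("a", "a", "b", "b")), "non-positive")
  expect_warning(cv_within(c(1, 2, 3), c("a", "a", "b")), "single-session")
  expect_error(cv_between(c(1, 2), c("a", "a")), ">= 2 subjects")
})

test_that("CVs are invariant to rescaling all values", {
  set.seed(9)
  v <- abs(rnorm(12, 10))
  s <- rep(letters[1:4], each = 3)
  expect_equal(cv_within(3.7 * v, s), cv_within(v, s), tolerance = 1e-12)
  expect_equal(cv_between(3.7 * v, s), cv_between(v, s), tolerance = 1e-12)
})

test_that("analyze_cell agrees across scopes when they coincide and recovers truth", {
  # zero within-subject variance: icc = 1, cvw = 0
  co0 <- simulate_cohort(one_measure_params(seed = 21, sigma_b = 0.5,
                                            sigma_w = 0, sigma_v = 0,
                                            n_subjects = 4, n_sessions = 2))
  r0 <- suppressWarnings(analyze_cell(co0, "m", B = 300, seed = 1))
  expect_equal(r0$icc, 1)
  expect_equal(r0$cvw_pct, 0)

  # whole-bundle equals the single-section scope when n_sections = 1
  co <- simulate_cohort(one_measure_params(seed = 22, n_subjects = 5,
                                           n_sessions = 3, sigma_v = 0.3))
  rw <- analyze_cell(co, "m", scope = "whole", B = 300, seed = 2)
  rs <- analyze_cell(co, "m", scope = "section", section = 1, B = 300, seed = 2)
  expect_equal(rs$icc, rw$icc)
  expect_equal(rs$cvw_pct, rw$cvw_pct)
  expect_equal(rs$n_voxels, rw$n_voxels)
})
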