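# Independent oracles and small fixtures used across test files.

# Brute-force 6-connected erosion by explicit neighbour loops.
naive_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nx <- x + off[1]; ny <- y + off[2]; nz <- z + off[3]
      if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] || nz > d[3] ||
          !mask[nx, ny, nz]) {
        keep <- FALSE
        break
      }
    }
    out[x, y, z] <- keep
  }
  out
}

# Scalar one-way ANOVA ICC with total-variance denominator, via stats::aov.
anova_icc <- function(y, subject) {
  fit <- stats::aov(y ~ factor(subject))
  msw <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  1 - msw / stats::var(y)
}

# One-measure simulation parameters used throughout: a small tube unless a
# test needs the 1000-voxel bundle of the recovery experiments.
one_measure_params <- function(seed, lambda = NULL, mu = 10, sigma_b = 1,
                               sigma_w = 1, sigma_v = 0.5, fwhm = 0,
                               n_subjects = 20, n_sessions = 5,
                               radius = 3, length = 12, n_sections = 1,
                               mask_jitter = 0, nufo_multi_fraction = 0.78) {
  if (!is.null(lambda)) {
    sigma_b <- sqrt(lambda)
    sigma_w <- sqrt(1 - lambda)
  }
  sim_params(n_subjects = n_subjects, n_sessions = n_sessions,
             radius = radius, length = length, n_sections = n_sections,
             mask_jitter = mask_jitter,
             nufo_multi_fraction = nufo_multi_fraction,
             measures = list(measure_spec("m", mu, sigma_b, sigma_w,
                                          sigma_v, fwhm)),
             seed = seed)
}

# Extract the records-by-voxels matrix of measure "m" and fit I2C2.
cohort_i2c2 <- function(cohort) {
  masks <- lapply(cohort$records, function(r) r$mask)
  maps <- lapply(cohort$records, function(r) r$measures$m)
  rm <- union_and_densify(maps, masks, record_subjects_vec(cohort))
  i2c2(rm)
}

record_subjects_vec <- function(cohort) {
  vapply(cohort$records, `[[`, "", "subject_id")
}

record_bundle_means <- function(cohort, measure = "m") {
  vapply(cohort$records,
         function(r) mean(r$measures[[measure]][r$mask], na.rm = TRUE), 0)
}

# Tiny arbitrary mask helper: logical array from linear indices.
mask_from_idx <- function(dim, idx) {
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  m
}
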