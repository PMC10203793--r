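#' Describe one synthetic measure
#'
#' A measure is simulated under the hierarchical model
#' `W_ij(v) = mu + T(v) + X_i + U_ij`, where `T(v)` is a fixed spatial texture
#' field with standard deviation `sigma_v` (optionally Gaussian-smoothed),
#' `X_i ~ N(0, sigma_b^2)` is a subject effect shared by all of subject `i`'s
#' sessions, and `U_ij ~ N(0, sigma_w^2)` is a session effect. Under this
#' model the population image intraclass correlation is
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2)` and the expected within-subject
#' coefficient of variation of bundle means is approximately `sigma_w / mu`.
#'
#' @param name Measure name (used as map filename and table key).
#' @param mu Positive mean level (coefficients of variation require mu > 0).
#' @param sigma_b Between-subject standard deviation (>= 0).
#' @param sigma_w Within-subject (session) standard deviation (>= 0).
#' @param sigma_v Standard deviation of the fixed spatial texture (>= 0).
#' @param smooth_fwhm_vox Gaussian FWHM, in voxels, applied to the texture
#'   field; 0 leaves white spatial noise.
#' @return A `measure_spec` list.
#' @export
measure_spec <- function(name, mu, sigma_b, sigma_w, sigma_v = 0,
                         smooth_fwhm_vox = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be positive: coefficients of variation are undefined for ",
         "non-positive means", call. = FALSE)
  }
  for (s in c(sigma_b = sigma_b, sigma_w = sigma_w, sigma_v = sigma_v,
              smooth_fwhm_vox = smooth_fwhm_vox)) {
    if (!is.numeric(s) || !is.finite(s) || s < 0) {
      stop("standard deviations and FWHM must be non-negative scalars",
           call. = FALSE)
    }
  }
  structure(list(name = name, mu = mu, sigma_b = sigma_b, sigma_w = sigma_w,
                 sigma_v = sigma_v, smooth_fwhm_vox = smooth_fwhm_vox),
            class = "measure_spec")
}

#' Default synthetic measures
#'
#' Three measures spanning the reliability range typically reported for
#' diffusion and magnetization-transfer white-matter maps: an FA-like measure
#' with high reliability (population I2C2 ~ 0.86), an ISOvf-like measure with
#' moderate reliability (~ 0.57) and low mean, and an ihMTR-like measure with
#' lower reliability (~ 0.43).
#'
#' @return A named list of [measure_spec()] objects.
#' @export
default_measures <- function() {
  list(
    fa    = measure_spec("fa",    mu = 0.5,  sigma_b = 0.05,  sigma_w = 0.02,
                         sigma_v = 0.05, smooth_fwhm_vox = 2),
    isovf = measure_spec("isovf", mu = 0.06, sigma_b = 0.008, sigma_w = 0.007,
                         sigma_v = 0.01, smooth_fwhm_vox = 2),
    ihmtr = measure_spec("ihmtr", mu = 10,   sigma_b = 0.7,   sigma_w = 0.8,
                         sigma_v = 0.8,  smooth_fwhm_vox = 2)
  )
}

#' Simulation parameters for a synthetic longitudinal cohort
#'
#' Ground-truth variance components, bundle geometry and mask perturbation
#' for [simulate_cohort()]. Defaults mirror a 20-subject, five-session
#' scan-rescan cohort with a ten-section bundle large enough that each
#' section clears the section-level volume threshold used in quality control.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions Sessions per subject: a scalar for a balanced design or
#'   an integer vector of length `n_subjects` (each >= 1, at least one
#'   subject with >= 2 sessions).
#' @param measures Named list of [measure_spec()] objects.
#' @param radius Tube radius in voxels.
#' @param length Tube length in voxels along the third grid axis.
#' @param n_sections Number of along-bundle sections (default 10).
#' @param nufo_multi_fraction Proportion of in-mask voxels carrying two or
#'   more fiber populations; the default 0.78 sits mid-range of the reported
#'   66--90% multi-fiber prevalence in white matter.
#' @param mask_jitter Per-voxel probability of flipping a boundary voxel of
#'   the bundle mask, independently per session (controls expected Dice).
#' @param grid Optional [voxel_grid()]; by default a grid that fits the tube
#'   with a two-voxel margin.
#' @param seed Integer seed; identical parameters (including the seed) yield
#'   bit-identical datasets.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_subjects = 20, n_sessions = 5,
                       measures = default_measures(),
                       radius = 9, length = 50, n_sections = 10,
                       nufo_multi_fraction = 0.78, mask_jitter = 0.1,
                       grid = NULL, seed = 1) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop("`n_subjects` must be an integer >= 2", call. = FALSE)
  }
  n_sessions <- as.integer(n_sessions)
  if (length(n_sessions) == 1L) n_sessions <- rep(n_sessions, n_subjects)
  if (length(n_sessions) != n_subjects || any(is.na(n_sessions)) ||
      any(n_sessions < 1L)) {
    stop("`n_sessions` must be a positive scalar or an integer vector of ",
         "length `n_subjects`", call. = FALSE)
  }
  if (max(n_sessions) < 2L) {
    stop("at least one subject needs >= 2 sessions", call. = FALSE)
  }
  if (!is.list(measures) || length(measures) == 0L ||
      !all(vapply(measures, inherits, TRUE, "measure_spec"))) {
    stop("`measures` must be a non-empty list of measure_spec objects",
         call. = FALSE)
  }
  names(measures) <- vapply(measures, `[[`, "", "name")
  if (anyDuplicated(names(measures))) {
    stop("measure names must be unique", call. = FALSE)
  }
  if (!is.numeric(nufo_multi_fraction) || nufo_multi_fraction < 0 ||
      nufo_multi_fraction > 1) {
    stop("`nufo_multi_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(mask_jitter) || mask_jitter < 0 || mask_jitter > 1) {
    stop("`mask_jitter` must lie in [0, 1]", call. = FALSE)
  }
  radius <- as.integer(radius)
  length <- as.integer(length)
  n_sections <- as.integer(n_sections)
  if (radius < 1L || length < 1L) {
    stop("`radius` and `length` must be positive", call. = FALSE)
  }
  if (n_sections < 1L || n_sections > length) {
    stop("`n_sections` must lie in [1, tube length]", call. = FALSE)
  }
  if (is.null(grid)) {
    side <- 2L * radius + 5L
    grid <- voxel_grid(c(side, side, length + 4L))
  }
  stopifnot(inherits(grid, "voxel_grid"))
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 measures = measures, radius = radius, length = length,
                 n_sections = n_sections,
                 nufo_multi_fraction = nufo_multi_fraction,
                 mask_jitter = mask_jitter, grid = grid,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Build the synthetic bundle geometry
#'
#' Places a straight cylindrical tube along the third grid axis and splits it
#' into `n_sections` contiguous, equal-length slabs along that axis (the
#' along-bundle sections of a tract profile). When the tube length is not a
#' multiple of the section count, remainder slices are assigned to the last
#' section.
#'
#' @param params A [sim_params()] object.
#' @return A list with `mask` (logical 3D array) and `labels` (integer 3D
#'   array; 0 outside the mask, 1..n_sections inside).
#' @examples
#' g <- generate_bundle_geometry(sim_params(radius = 2, length = 10,
#'                                          n_sections = 5))
#' sum(g$mask)
#' @export
generate_bundle_geometry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  shape <- params$grid$shape
  r <- params$radius
  len <- params$length
  if (2L * r + 1L > shape[1L]) {
    stop("tube diameter ", 2L * r + 1L, " exceeds grid x extent ", shape[1L],
         call. = FALSE)
  }
  if (2L * r + 1L > shape[2L]) {
    stop("tube diameter ", 2L * r + 1L, " exceeds grid y extent ", shape[2L],
         call. = FALSE)
  }
  if (len > shape[3L]) {
    stop("tube length ", len, " exceeds grid z extent ", shape[3L],
         call. = FALSE)
  }
  cx <- (shape[1L] + 1) / 2
  cy <- (shape[2L] + 1) / 2
  z0 <- (shape[3L] - len) %/% 2L + 1L
  dx2 <- (seq_len(shape[1L]) - cx)^2
  dy2 <- (seq_len(shape[2L]) - cy)^2
  disc <- outer(dx2, dy2, `+`) <= r^2
  inz <- logical(shape[3L])
  inz[z0:(z0 + len - 1L)] <- TRUE
  mask <- array(FALSE, shape)
  mask[, , inz] <- disc  # recycled slice-wise along z
  # Section index per in-tube slice: floor partition, remainder to the last.
  base <- len %/% params$n_sections
  zrel <- seq_len(len)
  lab_z <- pmin.int((zrel - 1L) %/% base + 1L, params$n_sections)
  labels <- array(0L, shape)
  for (k in seq_len(len)) {
    z <- z0 + k - 1L
    labels[, , z][disc] <- lab_z[k]
  }
  list(mask = mask, labels = labels)
}

#' Generate a number-of-fiber-orientations map
#'
#' Inside the mask, voxels carry one fiber population with probability
#' `1 - multi_fraction` and otherwise two or three (equal split); outside the
#' mask the count is zero.
#'
#' @param mask Logical 3D array.
#' @param multi_fraction Proportion of in-mask voxels with >= 2 populations.
#' @param seed Optional seed for reproducibility; `NULL` uses the current RNG
#'   stream (as [simulate_cohort()] does).
#' @return Integer 3D array of per-voxel fiber-population counts.
#' @export
generate_nufo_map <- function(mask, multi_fraction, seed = NULL) {
  if (!is.numeric(multi_fraction) || multi_fraction < 0 || multi_fraction > 1) {
    stop("`multi_fraction` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    nufo <- array(0L, dim(mask))
    idx <- which(mask)
    if (length(idx)) {
      multi <- stats::runif(length(idx)) < multi_fraction
      counts <- rep(1L, length(idx))
      counts[multi] <- ifelse(stats::runif(sum(multi)) < 0.5, 2L, 3L)
      nufo[idx] <- counts
    }
    nufo
  })
}

#' Perturb a bundle mask at its boundary
#'
#' Flips, independently with probability `p`, voxels on the 6-connected inner
#' surface (removed) and the 6-connected outer shell (added), emulating
#' session-to-session segmentation variability while keeping the mask
#' near-connected. Expected pairwise Dice decreases monotonically in `p`.
#'
#' @param mask Logical 3D array.
#' @param p Flip probability in \[0, 1\].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Logical 3D array.
#' @export
jitter_mask <- function(mask, p, seed = NULL) {
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  if (p == 0) return(mask)
  with_seed(seed, {
    inner <- which(mask & !erode_mask(mask, 1L))
    outer <- which(dilate_mask(mask, 1L) & !mask)
    out <- mask
    if (length(inner)) out[inner[stats::runif(length(inner)) < p]] <- FALSE
    if (length(outer)) out[outer[stats::runif(length(outer)) < p]] <- TRUE
    out
  })
}

# Per-record streamline-density surrogate: a radial taper (high in the tube
# core, falling to zero at the boundary) plus small session noise, clipped at
# zero and supported on the record's mask.
make_density_map <- function(mask, params) {
  shape <- params$grid$shape
  cx <- (shape[1L] + 1) / 2
  cy <- (shape[2L] + 1) / 2
  dx2 <- (seq_len(shape[1L]) - cx)^2
  dy2 <- (seq_len(shape[2L]) - cy)^2
  rr <- sqrt(outer(dx2, dy2, `+`))
  taper <- pmax(0, (params$radius + 1 - rr) / (params$radius + 1))
  dens <- array(rep(taper, shape[3L]), shape)
  dens <- dens + array(stats::rnorm(prod(shape), sd = 0.02), shape)
  dens <- pmax(dens, 0)
  dens[!mask] <- 0
  dens
}

#' Simulate a longitudinal scan-rescan cohort
#'
#' Generates, for every (subject, session) record: a jittered bundle mask,
#' a section label map, a number-of-fiber-orientations map, a density map,
#' and one 3D map per measure following the hierarchical model described in
#' [measure_spec()]. Measure values are `NaN` outside each record's mask.
#' The whole dataset is deterministic given `params` (including the seed).
#'
#' @param params A [sim_params()] object.
#' @return A `cohort_dataset`: list with `grid`, `records` (named
#'   `sub-XX_ses-YY`, each holding `subject_id`, `session_id`, `mask`,
#'   `sections`, `nufo`, `density` and `measures`), and `truth = params`.
#' @examples
#' p <- sim_params(n_subjects = 2, n_sessions = 2, radius = 2, length = 8,
#'                 n_sections = 2, measures = list(measure_spec("fa", 0.5, 0.05, 0.02)),
#'                 seed = 7)
#' cohort <- simulate_cohort(p)
#' names(cohort$records)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    geom <- generate_bundle_geometry(params)
    shape <- params$grid$shape
    nvox <- prod(shape)
    # Fixed spatial texture per measure, standardized to sd sigma_v.
    textures <- lapply(params$measures, function(m) {
      if (m$sigma_v <= 0) return(array(0, shape))
      tex <- array(stats::rnorm(nvox), shape)
      tex <- smooth_gaussian3d(tex, m$smooth_fwhm_vox)
      (tex - mean(tex)) / stats::sd(tex) * m$sigma_v
    })
    # Subject effects, one vector per measure.
    subj_fx <- lapply(params$measures, function(m) {
      stats::rnorm(params$n_subjects, sd = m$sigma_b)
    })
    records <- list()
    for (i in seq_len(params$n_subjects)) {
      sid <- sprintf("sub-%02d", i)
      for (j in seq_len(params$n_sessions[i])) {
        ses <- sprintf("ses-%02d", j)
        mask_ij <- jitter_mask(geom$mask, params$mask_jitter)
        nufo_ij <- generate_nufo_map(mask_ij, params$nufo_multi_fraction)
        dens_ij <- make_density_map(mask_ij, params)
        meas <- vector("list", length(params$measures))
        names(meas) <- names(params$measures)
        for (k in seq_along(params$measures)) {
          m <- params$measures[[k]]
          u_ij <- stats::rnorm(1L, sd = m$sigma_w)
          arr <- m$mu + textures[[k]] + subj_fx[[k]][i] + u_ij
          arr[!mask_ij] <- NaN
          meas[[k]] <- arr
        }
        records[[paste0(sid, "_", ses)]] <- list(
          subject_id = sid, session_id = ses,
          mask = mask_ij, sections = geom$labels, nufo = nufo_ij,
          density = dens_ij, measures = meas
        )
      }
    }
    cohort_dataset(params$grid, records, truth = params)
  })
}

#' Assemble a cohort dataset
#'
#' @param grid A [voxel_grid()].
#' @param records Named list of per-(subject, session) records; every array
#'   must match the grid shape and every record needs `subject_id`,
#'   `session_id`, `mask` and `measures`.
#' @param truth Optional [sim_params()] ground truth.
#' @return A `cohort_dataset`.
#' @export
cohort_dataset <- function(grid, records, truth = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.list(records) || length(records) == 0L) {
    stop("`records` must be a non-empty list", call. = FALSE)
  }
  for (nm in names(records)) {
    r <- records[[nm]]
    if (is.null(r$subject_id) || is.null(r$session_id) || is.null(r$mask)) {
      stop("record ", nm, " lacks subject_id/session_id/mask", call. = FALSE)
    }
    arrays <- c(list(r$mask), r$measures,
                Filter(Negate(is.null), list(r$sections, r$nufo, r$density)))
    for (a in arrays) {
      if (!identical(dim(a), grid$shape)) {
        stop("record ", nm, " holds an array off the cohort grid",
             call. = FALSE)
      }
    }
  }
  structure(list(grid = grid, records = records, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  subs <- unique(vapply(x$records, `[[`, "", "subject_id"))
  meas <- names(x$records[[1L]]$measures)
  cat("<cohort_dataset> ", length(subs), " subjects, ", length(x$records),
      " records, grid ", format(x$grid), "\n  measures: ",
      paste(meas, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Subject id per record, in record order.
record_subjects <- function(dataset) {
  vapply(dataset$records, `[[`, "", "subject_id")
}
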