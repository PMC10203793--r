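#' Mean measure value over a bundle mask
#'
#' Arithmetic mean of the valid (finite) in-mask voxel values.
#'
#' @param map Numeric 3D array.
#' @param mask Logical 3D array on the same grid.
#' @return Scalar mean.
#' @export
bundle_mean <- function(map, mask) {
  check_same_dim(map, mask, "map and mask")
  v <- map[which(mask)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no valid voxels under the mask", call. = FALSE)
  mean(v)
}

#' Between-measure correlation matrix, averaged over sessions
#'
#' For each session, computes the Pearson correlation between every pair of
#' measures across subjects' bundle means, then averages the per-session
#' matrices entrywise. Sessions where a measure has zero variance contribute
#' nothing to that measure's pairs (logged via message). The entrywise
#' arithmetic mean of r is the default; Fisher-z averaging is available.
#'
#' @param dataset A `cohort_dataset`.
#' @param measures Measure names; default all measures of the first record.
#' @param erode Safe-mask erosion applied to each record mask before
#'   averaging (0 = raw mask).
#' @param fisher_z Average atanh-transformed correlations instead of raw r.
#' @param min_subjects Minimum subjects per session (default 3).
#' @return A `correlation_matrix`: list with `r` (symmetric, unit diagonal),
#'   `per_session` (list of matrices), `measures`, `n_sessions_averaged`.
#' @export
measure_correlation <- function(dataset, measures = NULL, erode = 1L,
                                fisher_z = FALSE, min_subjects = 3L) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  measures <- measures %||% names(dataset$records[[1L]]$measures)
  if (length(measures) < 2L) stop("need >= 2 measures", call. = FALSE)
  sessions <- sort(unique(vapply(dataset$records, `[[`, "", "session_id")))
  per_session <- list()
  for (ses in sessions) {
    recs <- Filter(function(r) r$session_id == ses, dataset$records)
    if (length(recs) < min_subjects) {
      message("session ", ses, ": fewer than ", min_subjects,
              " subjects, skipped")
      next
    }
    M <- vapply(recs, function(r) {
      m <- if (erode > 0L) erode_mask(r$mask, erode) else r$mask
      vapply(measures, function(nm) bundle_mean(r$measures[[nm]], m), 0)
    }, numeric(length(measures)))
    M <- t(M)  # subjects x measures
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) {
      message("session ", ses, ": zero variance for ",
              paste(measures[sds == 0], collapse = ", "),
              "; affected pairs omitted for this session")
    }
    r <- suppressWarnings(stats::cor(M))
    dimnames(r) <- list(measures, measures)
    per_session[[ses]] <- r
  }
  if (!length(per_session)) stop("no session had enough subjects", call. = FALSE)
  k <- length(measures)
  stack <- array(unlist(per_session), dim = c(k, k, length(per_session)))
  if (fisher_z) {
    z <- atanh(pmin(pmax(stack, -1 + 1e-12), 1 - 1e-12))
    ravg <- tanh(apply(z, c(1L, 2L), mean, na.rm = TRUE))
  } else {
    ravg <- apply(stack, c(1L, 2L), mean, na.rm = TRUE)
  }
  diag(ravg) <- 1
  dimnames(ravg) <- list(measures, measures)
  structure(list(r = ravg, per_session = per_session, measures = measures,
                 n_sessions_averaged = length(per_session)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", length(x$measures), " measures, averaged over ",
      x$n_sessions_averaged, " sessions\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' One row per unordered measure pair with the session-averaged r and the
#' per-session values, ready for heatmap rendering or CSV export.
#'
#' @param x A `correlation_matrix`.
#' @return A data frame.
#' @export
correlation_long <- function(x) {
  stopifnot(inherits(x, "correlation_matrix"))
  meas <- x$measures
  pairs <- utils::combn(meas, 2L)
  out <- data.frame(measure_a = pairs[1L, ], measure_b = pairs[2L, ],
                    r_mean = apply(pairs, 2L, function(p) x$r[p[1L], p[2L]]),
                    stringsAsFactors = FALSE)
  for (ses in names(x$per_session)) {
    out[[paste0("r_", ses)]] <-
      apply(pairs, 2L, function(p) x$per_session[[ses]][p[1L], p[2L]])
  }
  out
}
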