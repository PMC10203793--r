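#' Dice similarity between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks agree on absence and
#' score 1, with a degeneracy warning.
#'
#' @param a,b Logical 3D arrays on the same grid.
#' @return Scalar in \[0, 1\].
#' @examples
#' m <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' dice(m, m)
#' @export
dice <- function(a, b) {
  check_same_dim(a, b, "masks")
  va <- sum(a)
  vb <- sum(b)
  if (va + vb == 0L) {
    warning("both masks empty: Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a & b) / (va + vb)
}

#' Pearson correlation between two density maps
#'
#' Correlates the two maps over a support mask (by default the union of their
#' non-zero voxels), treating out-of-mask density as 0. Undefined when either
#' map has zero variance over the support; that case returns `NA` with a
#' warning.
#'
#' @param a,b Numeric 3D arrays on the same grid.
#' @param support Logical 3D array; default `(a > 0) | (b > 0)`.
#' @return Scalar in \[-1, 1\], or `NA`.
#' @export
density_correlation <- function(a, b, support = NULL) {
  check_same_dim(a, b, "density maps")
  if (is.null(support)) {
    support <- binarize_density(a) | binarize_density(b)
  } else {
    check_same_dim(a, support, "map and support")
  }
  idx <- which(support)
  if (length(idx) < 2L) {
    warning("support has fewer than two voxels: correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  x <- a[idx]
  y <- b[idx]
  x[!is.finite(x)] <- 0
  y[!is.finite(y)] <- 0
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance over support: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Pairwise bundle-segmentation reproducibility
#'
#' For every subject with at least two sessions, computes the Dice score and
#' the density-map correlation for all unordered session pairs, using the raw
#' per-session masks (pre-erosion segmentation outputs). Subjects with a
#' single session are skipped with a message.
#'
#' @param dataset A `cohort_dataset` whose records carry `mask` and
#'   (optionally) `density`.
#' @return List with `pairs` (one row per subject x session pair), `subjects`
#'   (per-subject means) and `summary` (cohort mean/min/max of the
#'   per-subject means).
#' @export
pairwise_reproducibility <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  subj <- record_subjects(dataset)
  has_density <- !is.null(dataset$records[[1L]]$density)
  rows <- list()
  for (s in unique(subj)) {
    recs <- dataset$records[subj == s]
    if (length(recs) < 2L) {
      message("subject ", s, " has a single session: skipped")
      next
    }
    cmb <- utils::combn(length(recs), 2L)
    for (c_i in seq_len(ncol(cmb))) {
      ra <- recs[[cmb[1L, c_i]]]
      rb <- recs[[cmb[2L, c_i]]]
      dr <- if (has_density) {
        density_correlation(ra$density, rb$density, support = ra$mask | rb$mask)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, session_a = ra$session_id, session_b = rb$session_id,
        dice = dice(ra$mask, rb$mask), density_r = dr,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no subject has >= 2 sessions", call. = FALSE)
  pairs <- do.call(rbind, rows)
  agg <- function(v, f) as.numeric(tapply(v, pairs$subject_id, f))
  subjects <- data.frame(
    subject_id = sort(unique(pairs$subject_id)),
    n_pairs = as.integer(table(pairs$subject_id)[sort(unique(pairs$subject_id))]),
    mean_dice = agg(pairs$dice, mean),
    mean_density_r = agg(pairs$density_r, function(v) mean(v, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  summary <- data.frame(
    metric = c("dice", "density_r"),
    mean = c(mean(subjects$mean_dice), mean(subjects$mean_density_r, na.rm = TRUE)),
    min = c(min(subjects$mean_dice), suppressWarnings(min(subjects$mean_density_r, na.rm = TRUE))),
    max = c(max(subjects$mean_dice), suppressWarnings(max(subjects$mean_density_r, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  list(pairs = pairs, subjects = subjects, summary = summary)
}
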