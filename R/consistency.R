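#' Extract records over the union mask and densify missing voxels
#'
#' Builds the records-by-voxels matrix over the voxelwise union of all record
#' masks. A voxel missing from a record (outside its mask, or invalidated to
#' `NaN` by upstream thresholding) is imputed with the mean of the records in
#' which it is observed: the same subject's other sessions when at least one
#' of them observes the voxel, otherwise all observing records in the cohort.
#' Voxels observed in no record are dropped.
#'
#' @param maps List of numeric 3D arrays, one per record.
#' @param masks List of logical 3D arrays, one per record, same grid.
#' @param subject Character vector of subject ids, one per record.
#' @return A `record_matrix`: list with `values` (records x voxels, no
#'   missing entries), `subject`, `available` (logical matrix marking
#'   originally observed entries), `voxel_index` (linear indices into the
#'   grid) and `grid_dim`.
#' @export
union_and_densify <- function(maps, masks, subject) {
  n <- length(maps)
  if (n < 2L || length(masks) != n || length(subject) != n) {
    stop("need >= 2 records with one map, mask and subject id each",
         call. = FALSE)
  }
  if (length(unique(subject)) < 2L) {
    stop("need >= 2 subjects", call. = FALSE)
  }
  for (r in seq_len(n)) check_same_dim(maps[[r]], masks[[r]], "map and mask")
  for (r in seq.int(2L, n)) check_same_dim(masks[[1L]], masks[[r]], "record masks")

  union <- Reduce(`|`, masks)
  idx <- which(union)
  if (length(idx) == 0L) stop("no analyzable voxels", call. = FALSE)

  X <- do.call(rbind, lapply(maps, function(a) a[idx]))
  A <- do.call(rbind, lapply(masks, function(m) m[idx])) & is.finite(X)

  seen <- colSums(A) > 0L
  if (!any(seen)) stop("no analyzable voxels", call. = FALSE)
  if (!all(seen)) {
    X <- X[, seen, drop = FALSE]
    A <- A[, seen, drop = FALSE]
    idx <- idx[seen]
  }

  if (!all(A)) {
    Xz <- X
    Xz[!A] <- 0
    grp <- factor(subject, levels = unique(subject))
    ssum <- rowsum(Xz, grp)
    scnt <- rowsum(A + 0, grp)
    smean <- ssum / scnt                       # NaN where a subject never sees a voxel
    cmean <- colSums(Xz) / colSums(A)          # cohort fallback
    fill <- smean[as.integer(grp), , drop = FALSE]
    miss_subj <- is.nan(fill)
    fill[miss_subj] <- matrix(cmean, nrow(fill), ncol(fill), byrow = TRUE)[miss_subj]
    X[!A] <- fill[!A]
  }

  imputed <- mean(!A)
  if (imputed > 0.5) {
    warning(sprintf("densification imputed %.1f%% of entries (> 50%%)",
                    100 * imputed), call. = FALSE)
  }
  structure(list(values = X, subject = subject, available = A,
                 voxel_index = idx, grid_dim = dim(masks[[1L]])),
            class = "record_matrix")
}

#' @export
print.record_matrix <- function(x, ...) {
  cat("<record_matrix> ", nrow(x$values), " records x ", ncol(x$values),
      " voxels, ", length(unique(x$subject)), " subjects, ",
      sprintf("%.1f%% imputed\n", 100 * mean(!x$available)), sep = "")
  invisible(x)
}

# Normalize i2c2-style input: record_matrix, matrix + subject, or vector +
# subject (single-voxel images).
as_record_values <- function(x, subject) {
  if (inherits(x, "record_matrix")) {
    list(values = x$values, subject = x$subject)
  } else {
    if (is.null(subject)) stop("`subject` is required", call. = FALSE)
    v <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
    if (nrow(v) != length(subject)) {
      stop("one subject id per record row is required", call. = FALSE)
    }
    list(values = v, subject = as.character(subject))
  }
}

#' Image intraclass correlation coefficient (I2C2)
#'
#' Method-of-moments trace-ratio estimator of the one-way random-effects,
#' absolute-agreement intraclass correlation generalized to vectorized
#' images:
#' \deqn{\hat\lambda = 1 - T_w / T_t,}
#' where, with \eqn{\bar W_i} the per-subject mean image, \eqn{\bar W} the
#' grand mean image, N records and I subjects,
#' \eqn{T_w = \sum_{ij} \|W_{ij} - \bar W_i\|^2 / (N - I)} and
#' \eqn{T_t = \sum_{ij} \|W_{ij} - \bar W\|^2 / (N - 1)}, norms summed over
#' voxels. On single-voxel images this reduces to the classical scalar
#' one-way ICC with total-variance denominator. The estimate is at most 1 and
#' may be negative; if all records are identical (\eqn{T_t = 0}) the value is
#' defined as 1 with a degeneracy warning.
#'
#' @param x A `record_matrix` from [union_and_densify()], or a numeric matrix
#'   (records x voxels) or vector (one voxel) with `subject` supplied.
#' @param subject Subject id per record (ignored for `record_matrix` input).
#' @return Unitless scalar estimate.
#' @examples
#' i2c2(c(1, 1, 3, 3), subject = c("a", "a", "b", "b"))
#' @export
i2c2 <- function(x, subject = NULL) {
  d <- as_record_values(x, subject)
  X <- d$values
  grp <- factor(d$subject, levels = unique(d$subject))
  N <- nrow(X)
  I <- nlevels(grp)
  if (I < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (N <= I) stop("need >= 1 subject with >= 2 records", call. = FALSE)
  cnt <- tabulate(grp, I)
  smean <- rowsum(X, grp) / cnt
  Tw <- sum((X - smean[as.integer(grp), , drop = FALSE])^2) / (N - I)
  gmean <- colMeans(X)
  Tt <- sum(sweep(X, 2L, gmean)^2) / (N - 1)
  if (Tt <= 0) {
    warning("all records identical: total variability is zero, I2C2 set to 1",
            call. = FALSE)
    return(1)
  }
  1 - Tw / Tt
}

#' Within-subject coefficient of variation
#'
#' The coefficient of variation is computed per subject over that subject's
#' session values (sample standard deviation over mean), then averaged across
#' subjects. Subjects with a single session carry no within-subject
#' information and are excluded with a warning.
#'
#' @param values Positive scalar per record (e.g. bundle means).
#' @param subject Subject id per record.
#' @return CVw in percent.
#' @examples
#' cv_within(c(9, 10, 11), subject = c("a", "a", "a"), min_subjects = 1)
#' @param min_subjects Minimum number of usable subjects (default 1).
#' @export
cv_within <- function(values, subject, min_subjects = 1L) {
  stopifnot(length(values) == length(subject))
  by_subj <- split(as.numeric(values), subject)
  nses <- vapply(by_subj, length, 0L)
  if (any(nses < 2L)) {
    warning(sum(nses < 2L), " single-session subject(s) excluded from CVw",
            call. = FALSE)
    by_subj <- by_subj[nses >= 2L]
  }
  if (length(by_subj) < min_subjects) {
    stop("not enough subjects with >= 2 sessions", call. = FALSE)
  }
  means <- vapply(by_subj, mean, 0)
  if (any(means <= 0)) {
    stop("non-positive subject mean: coefficient of variation undefined",
         call. = FALSE)
  }
  cv_i <- vapply(by_subj, stats::sd, 0) / means
  100 * mean(cv_i)
}

#' Between-subject coefficient of variation
#'
#' Each subject is first averaged session-wise; the coefficient of variation
#' (sample standard deviation over mean) is then taken across those
#' per-subject averages.
#'
#' @inheritParams cv_within
#' @return CVb in percent.
#' @examples
#' cv_between(c(1, 2), subject = c("a", "b"))
#' @export
cv_between <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  m_i <- vapply(split(as.numeric(values), subject), mean, 0)
  if (length(m_i) < 2L) stop("need >= 2 subjects", call. = FALSE)
  gm <- mean(m_i)
  if (gm <= 0) {
    stop("non-positive grand mean: coefficient of variation undefined",
         call. = FALSE)
  }
  100 * stats::sd(m_i) / gm
}
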