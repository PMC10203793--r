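#' Binarize a density map
#'
#' A voxel enters the mask iff its density strictly exceeds `threshold`;
#' `NaN`/`NA` densities never do. The default threshold 0 keeps every voxel
#' visited by at least one streamline.
#'
#' @param density Numeric 3D array.
#' @param threshold Non-negative scalar.
#' @return Logical 3D array.
#' @export
binarize_density <- function(density, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a non-negative scalar", call. = FALSE)
  }
  out <- density > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Erode a binary mask
#'
#' Morphological erosion with a 6-connected (face-adjacency) structuring
#' element, applied `iterations` times. One iteration yields the
#' conservative "safe mask" that trims the partial-volume shell of a bundle.
#' Eroding k then m times equals eroding k+m times, and the result is always
#' a subset of the input; the result may be empty.
#'
#' @param mask Logical 3D array.
#' @param iterations Positive integer (default 1).
#' @return Logical 3D array.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  out <- mask
  for (it in seq_len(iterations)) {
    m <- out
    for (axis in 1:3) {
      out <- out & shift_along(m, axis, 1L) & shift_along(m, axis, -1L)
    }
  }
  out
}

#' Dilate a binary mask (6-connectivity)
#'
#' Companion to [erode_mask()]; used to find the outer shell when jittering
#' mask boundaries.
#'
#' @inheritParams erode_mask
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  out <- mask
  for (it in seq_len(iterations)) {
    m <- out
    for (axis in 1:3) {
      out <- out | shift_along(m, axis, 1L) | shift_along(m, axis, -1L)
    }
  }
  out
}

#' Merge left and right hemisphere masks
#'
#' Voxelwise union of two masks on the same grid.
#'
#' @param left,right Logical 3D arrays of identical shape.
#' @return Logical 3D array.
#' @export
merge_lr <- function(left, right) {
  check_same_dim(left, right, "left/right masks")
  left | right
}

#' Intersect section labels with a safe mask
#'
#' Returns one mask per section label `k`, equal to `labels == k` intersected
#' with `safe`. Sections may come back empty; when the labels cover the safe
#' mask the section masks partition it.
#'
#' @param safe Logical 3D array (typically the eroded bundle mask).
#' @param labels Integer 3D array, 0 = background, 1..K = section index.
#' @param n_sections Number of sections K; defaults to `max(labels)`.
#' @return Named list of logical 3D arrays (`section_1` .. `section_K`).
#' @export
split_sections <- function(safe, labels, n_sections = NULL) {
  check_same_dim(safe, labels, "safe mask and label map")
  K <- as.integer(n_sections %||% max(labels))
  if (K < 1L) stop("label map contains no sections", call. = FALSE)
  out <- lapply(seq_len(K), function(k) safe & (labels == k))
  names(out) <- paste0("section_", seq_len(K))
  out
}

#' Split a mask into single- and multi-fiber compartments
#'
#' Thresholds the number-of-fiber-orientations map at 1 and >= 2: the single
#' compartment keeps in-mask voxels with exactly one fiber population, the
#' multi compartment those with two or more. Voxels with a zero count drop
#' out of both, so `single` and `multi` are disjoint subsets of `mask`.
#'
#' @param mask Logical 3D array.
#' @param nufo Integer 3D array of per-voxel fiber-population counts.
#' @return List with logical arrays `single` and `multi`.
#' @export
compartmentalize <- function(mask, nufo) {
  check_same_dim(mask, nufo, "mask and NuFO map")
  list(single = mask & (nufo == 1L), multi = mask & (nufo >= 2L))
}

#' Volume-based quality control
#'
#' Excludes analysis units whose mean mask volume across records falls
#' strictly below the threshold for their scope: 1000 voxels for along-bundle
#' sections, 400 for fiber-population compartments. Units exactly at the
#' threshold are kept.
#'
#' @param volumes Named numeric vector of mean volumes (voxels) per unit.
#' @param scope `"section"` or `"compartment"` (selects the threshold).
#' @param thresholds Named thresholds, overridable for sensitivity analyses.
#' @return List with `kept` and `excluded` unit names and `log`, a data frame
#'   (unit, scope, mean_volume, threshold, excluded).
#' @examples
#' apply_volume_qc(c(s1 = 1200, s2 = 999), "section")$excluded
#' @export
apply_volume_qc <- function(volumes, scope,
                            thresholds = c(section = 1000, compartment = 400)) {
  if (any(volumes < 0, na.rm = TRUE)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  if (length(scope) != 1L || !scope %in% names(thresholds)) {
    stop("unknown scope '", paste(scope, collapse = ","), "'; expected one of ",
         paste(names(thresholds), collapse = ", "), call. = FALSE)
  }
  thr <- unname(thresholds[[scope]])
  excluded <- volumes < thr
  log <- data.frame(unit = names(volumes) %||% as.character(seq_along(volumes)),
                    scope = scope, mean_volume = as.numeric(volumes),
                    threshold = thr, excluded = unname(excluded),
                    stringsAsFactors = FALSE)
  list(kept = log$unit[!excluded], excluded = log$unit[excluded], log = log)
}

#' Invalidate low isotropic-volume-fraction voxels
#'
#' Voxels with values strictly below `cutoff` become `NaN` and are thereby
#' excluded from every downstream statistic (the exclusion is an
#' invalidation, not a clipping). Intended for ISOvf-like maps whose
#' near-zero values are unreliable; the default cutoff is 0.045.
#'
#' @param map Numeric 3D array (or any numeric array/vector).
#' @param cutoff Non-negative scalar.
#' @return The map with sub-cutoff voxels set to `NaN`.
#' @export
threshold_isovf <- function(map, cutoff = 0.045) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0) {
    stop("`cutoff` must be a non-negative scalar", call. = FALSE)
  }
  if (cutoff == 0) return(map)
  map[which(map < cutoff)] <- NaN
  map
}

#' Mask volume
#'
#' @param mask Logical array.
#' @return Integer count of `TRUE` voxels.
#' @export
mask_volume <- function(mask) sum(mask, na.rm = TRUE)
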