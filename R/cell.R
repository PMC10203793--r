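# One analysis "cell" = (measure, scope, compartment): the unit at which
# consistency is reported.

# Build the per-record analysis mask for a cell: safe mask (eroded record
# mask), intersected with the section label and/or fiber-population
# compartment as requested.
cell_masks <- function(dataset, scope = "whole", section = NULL,
                       compartment = "average", erode = 1L) {
  lapply(dataset$records, function(r) {
    m <- if (erode > 0L) erode_mask(r$mask, erode) else r$mask
    if (scope == "section") {
      if (is.null(r$sections)) stop("records carry no section labels", call. = FALSE)
      m <- m & (r$sections == section)
    }
    if (compartment != "average") {
      if (is.null(r$nufo)) stop("records carry no NuFO map", call. = FALSE)
      m <- if (compartment == "single") m & (r$nufo == 1L) else m & (r$nufo >= 2L)
    }
    m
  })
}

# Core computation shared by analyze_cell() and the pipeline: densify,
# I2C2 + BCa, and CVs on per-record spatial means of the densified cell.
analyze_records <- function(maps, masks, subject, B = 2000L, alpha = 0.05,
                            seed = NULL) {
  rm <- union_and_densify(maps, masks, subject)
  boot <- i2c2_bca(rm, B = B, alpha = alpha, seed = seed)
  means <- rowMeans(rm$values)
  list(icc = boot$estimate, ci_low = boot$ci_low, ci_high = boot$ci_high,
       p_value = boot$p_value,
       cvw_pct = cv_within(means, subject),
       cvb_pct = cv_between(means, subject),
       n_subjects = length(unique(subject)), n_records = nrow(rm$values),
       n_voxels = ncol(rm$values), imputed_fraction = mean(!rm$available))
}

#' Consistency of one (measure, scope, compartment) cell
#'
#' Builds each record's analysis mask (safe mask, intersected with the
#' requested along-bundle section and/or fiber-population compartment),
#' invalidates sub-cutoff ISOvf voxels where applicable, densifies the
#' records over the union mask, and reports voxel-level I2C2 with BCa
#' bootstrap inference plus within-/between-subject coefficients of
#' variation computed on per-record spatial means of the densified cell.
#'
#' @param dataset A `cohort_dataset`.
#' @param measure Measure name present in every record.
#' @param scope `"whole"` for the whole bundle or `"section"` with `section`.
#' @param section Section index (required when `scope = "section"`).
#' @param compartment `"average"` (all voxels), `"single"` (one fiber
#'   population) or `"multi"` (two or more).
#' @param erode Safe-mask erosion iterations applied to each record mask.
#' @param isovf_cutoff Invalidation cutoff applied to measures named in
#'   `isovf_measures` (default 0.045; 0 disables).
#' @param isovf_measures Measure names subject to the cutoff.
#' @param B,alpha,seed Bootstrap settings, see [bca_bootstrap()].
#' @return A `consistency_result` list: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `cvw_pct`, `cvb_pct`, `n_subjects`, `n_records`, `n_voxels`,
#'   `imputed_fraction` plus the cell coordinates.
#' @export
analyze_cell <- function(dataset, measure, scope = c("whole", "section"),
                         section = NULL,
                         compartment = c("average", "single", "multi"),
                         erode = 1L, isovf_cutoff = 0.045,
                         isovf_measures = "isovf",
                         B = 2000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  scope <- match.arg(scope)
  compartment <- match.arg(compartment)
  if (scope == "section" && is.null(section)) {
    stop("`section` is required when scope = \"section\"", call. = FALSE)
  }
  masks <- cell_masks(dataset, scope, section, compartment, erode)
  maps <- lapply(dataset$records, function(r) {
    a <- r$measures[[measure]]
    if (is.null(a)) {
      stop("measure '", measure, "' missing from record ",
           r$subject_id, "_", r$session_id, call. = FALSE)
    }
    if (measure %in% isovf_measures && isovf_cutoff > 0) {
      a <- threshold_isovf(a, isovf_cutoff)
    }
    a
  })
  subject <- record_subjects(dataset)
  res <- analyze_records(maps, masks, subject, B = B, alpha = alpha, seed = seed)
  structure(c(list(measure = measure, scope = scope,
                   section = if (scope == "section") as.integer(section) else NA_integer_,
                   compartment = compartment), res),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  loc <- if (x$scope == "whole") "whole bundle" else paste("section", x$section)
  cat(sprintf("%s | %s | %s\n", x$measure, loc, x$compartment))
  cat(sprintf("  I2C2 %.3f [%.3f, %.3f], p = %.4g\n",
              x$icc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  CVw %.2f%%, CVb %.2f%% (%d subjects, %d records, %d voxels, %.1f%% imputed)\n",
              x$cvw_pct, x$cvb_pct, x$n_subjects, x$n_records, x$n_voxels,
              100 * x$imputed_fraction))
  invisible(x)
}

#' @export
as.data.frame.consistency_result <- function(x, ...) {
  data.frame(measure = x$measure, scope = x$scope, section = x$section,
             compartment = x$compartment, icc = x$icc, ci_low = x$ci_low,
             ci_high = x$ci_high, p_value = x$p_value, cvw_pct = x$cvw_pct,
             cvb_pct = x$cvb_pct, n_subjects = x$n_subjects,
             n_records = x$n_records, n_voxels = x$n_voxels,
             imputed_fraction = x$imputed_fraction,
             stringsAsFactors = FALSE)
}
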