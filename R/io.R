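#' Write a cohort to a NIfTI-1 directory tree
#'
#' Layout: `<dir>/sub-XX/ses-YY/{mask,sections,nufo,density,<measure>}.nii.gz`
#' plus a `manifest.json` recording measure names and, when present, the
#' ground-truth simulation parameters. Masks, section labels and NuFO maps
#' are stored as uint8; measure and density maps as float64 by default so
#' that a written-then-read cohort reproduces in-memory statistics exactly
#' (`datatype = "float"` gives float32 files at the cost of rounding).
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @param datatype RNifti datatype for measure/density maps.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir, datatype = "double") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- dataset$grid$voxel_size_mm
  wr <- function(arr, path, dt) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(vs, 3L)
    RNifti::writeNifti(img, path, datatype = dt)
  }
  for (r in dataset$records) {
    rdir <- file.path(dir, r$subject_id, r$session_id)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    wr(array(as.integer(r$mask), dim(r$mask)), file.path(rdir, "mask.nii.gz"), "uint8")
    if (!is.null(r$sections)) {
      wr(r$sections, file.path(rdir, "sections.nii.gz"), "uint8")
    }
    if (!is.null(r$nufo)) {
      wr(r$nufo, file.path(rdir, "nufo.nii.gz"), "uint8")
    }
    if (!is.null(r$density)) {
      wr(r$density, file.path(rdir, "density.nii.gz"), datatype)
    }
    for (nm in names(r$measures)) {
      wr(r$measures[[nm]], file.path(rdir, paste0(nm, ".nii.gz")), datatype)
    }
  }
  manifest <- list(
    format = "wmconsist-cohort/1",
    grid = list(shape = dataset$grid$shape,
                voxel_size_mm = dataset$grid$voxel_size_mm,
                origin = dataset$grid$origin),
    measures = names(dataset$records[[1L]]$measures),
    records = lapply(unname(dataset$records), function(r) {
      list(subject_id = r$subject_id, session_id = r$session_id)
    }),
    truth = if (!is.null(dataset$truth)) sim_params_to_list(dataset$truth)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a NIfTI-1 directory tree
#'
#' Inverse of [write_cohort()]; restores the grid, per-record maps and the
#' ground-truth parameters when the manifest carries them.
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  grid <- voxel_grid(mf$grid$shape, mf$grid$voxel_size_mm, mf$grid$origin)
  rd <- function(path) {
    a <- RNifti::readNifti(path)
    array(as.vector(a), dim(a))
  }
  records <- list()
  recs <- mf$records  # data frame after simplification
  missing <- character()
  for (k in seq_len(nrow(recs))) {
    sid <- recs$subject_id[k]
    ses <- recs$session_id[k]
    rdir <- file.path(dir, sid, ses)
    meas <- list()
    for (nm in mf$measures) {
      p <- file.path(rdir, paste0(nm, ".nii.gz"))
      if (!file.exists(p)) {
        missing <- c(missing, p)
        next
      }
      meas[[nm]] <- rd(p)
    }
    opt <- function(name) {
      p <- file.path(rdir, paste0(name, ".nii.gz"))
      if (file.exists(p)) rd(p) else NULL
    }
    mask_p <- file.path(rdir, "mask.nii.gz")
    if (!file.exists(mask_p)) missing <- c(missing, mask_p)
    if (length(missing)) next
    sections <- opt("sections")
    nufo <- opt("nufo")
    records[[paste0(sid, "_", ses)]] <- list(
      subject_id = sid, session_id = ses,
      mask = rd(mask_p) > 0.5,
      sections = if (!is.null(sections)) array(as.integer(round(sections)), grid$shape),
      nufo = if (!is.null(nufo)) array(as.integer(round(nufo)), grid$shape),
      density = opt("density"),
      measures = meas)
  }
  if (length(missing)) {
    stop("missing map files:\n  ", paste(missing, collapse = "\n  "),
         call. = FALSE)
  }
  truth <- if (!is.null(mf$truth)) sim_params_from_list(mf$truth)
  cohort_dataset(grid, records, truth = truth)
}

# Serialize sim_params to plain lists for the JSON manifest and back.
sim_params_to_list <- function(p) {
  list(n_subjects = p$n_subjects, n_sessions = p$n_sessions,
       measures = lapply(unname(p$measures), unclass),
       radius = p$radius, length = p$length, n_sections = p$n_sections,
       nufo_multi_fraction = p$nufo_multi_fraction,
       mask_jitter = p$mask_jitter,
       grid = list(shape = p$grid$shape,
                   voxel_size_mm = p$grid$voxel_size_mm,
                   origin = p$grid$origin),
       seed = p$seed)
}

sim_params_from_list <- function(l) {
  measures <- lapply(seq_len(nrow(l$measures)), function(i) {
    m <- l$measures[i, ]
    measure_spec(m$name, m$mu, m$sigma_b, m$sigma_w, m$sigma_v,
                 m$smooth_fwhm_vox)
  })
  sim_params(n_subjects = l$n_subjects, n_sessions = l$n_sessions,
             measures = measures, radius = l$radius, length = l$length,
             n_sections = l$n_sections,
             nufo_multi_fraction = l$nufo_multi_fraction,
             mask_jitter = l$mask_jitter,
             grid = voxel_grid(l$grid$shape, l$grid$voxel_size_mm,
                               l$grid$origin),
             seed = l$seed)
}
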