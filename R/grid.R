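#' Define the common voxel grid
#'
#' All maps and masks in a cohort share one isotropic grid, playing the role
#' of the population template space in which registered measure maps live.
#'
#' @param shape Integer vector of length 3, array dimensions (all >= 1).
#' @param voxel_size_mm Positive isotropic voxel size in millimetres.
#' @param origin Numeric length-3 world-space origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(c(16, 16, 31))
#' @export
voxel_grid <- function(shape, voxel_size_mm = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L || voxel_size_mm <= 0) {
    stop("`voxel_size_mm` must be a positive scalar", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite scalars", call. = FALSE)
  }
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " @ ", x$voxel_size_mm, " mm isotropic\n", sep = "")
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), "@", x$voxel_size_mm, "mm")
}
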