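# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream. A `NULL`
#' seed evaluates `code` against the ambient stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# padding with `fill`. out[..., i, ...] <- x[..., i + dir, ...].
shift_along <- function(x, axis, dir, fill = FALSE) {
  d <- dim(x)
  n <- d[axis]
  out <- array(fill, d)
  if (n < 2L) return(out)
  dst <- lapply(d, seq_len)
  src <- dst
  if (dir > 0) {
    dst[[axis]] <- seq_len(n - 1L)
    src[[axis]] <- seq.int(2L, n)
  } else {
    dst[[axis]] <- seq.int(2L, n)
    src[[axis]] <- seq_len(n - 1L)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- x[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Separable Gaussian smoothing of a 3D array; FWHM in voxels, 0 = no-op.
# Edge handling renormalizes the truncated kernel so flat fields stay flat.
smooth_gaussian3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    K <- outer(seq_len(n), seq_len(n), function(i, j) stats::dnorm(j - i, sd = sigma))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(arr, perm)
    dim(x) <- c(n, prod(d[perm][-1L]))
    x <- K %*% x
    dim(x) <- d[perm]
    arr <- aperm(x, order(perm))
  }
  arr
}

# Small string fingerprint for provenance manifests (no cryptographic claims).
config_fingerprint <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop("grid mismatch: ", what, " have shapes ",
         paste(dim(a), collapse = "x"), " and ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  }
  invisible(TRUE)
}
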