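# Subject-level nonparametric bootstrap with BCa intervals.
#
# The resampling unit is always the subject: all of a subject's sessions move
# together, which preserves the within-subject correlation the statistics are
# about. Confidence intervals use the accelerated bias-corrected percentile
# method: bias correction z0 from the share of bootstrap replicates below the
# point estimate, acceleration a from the skewness of leave-one-subject-out
# jackknife values.

# Shared endpoint/p-value computation given the three ingredient samples.
bca_from_samples <- function(theta_hat, theta_star, theta_jack,
                             alpha = 0.05, null_value = 0) {
  B <- length(theta_star)
  if (B < 2L) stop("need a bootstrap sample", call. = FALSE)
  rng <- range(theta_star)
  if (rng[2L] - rng[1L] < .Machine$double.eps^0.75) {
    warning("degenerate bootstrap distribution: all replicates equal; ",
            "interval collapses to a point", call. = FALSE)
    pt <- theta_star[1L]
    return(list(ci_low = pt, ci_high = pt,
                p_value = if (abs(pt - null_value) > 0) 0 else 1,
                z0 = 0, accel = 0))
  }
  prop <- mean(theta_star < theta_hat)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  d <- mean(theta_jack) - theta_jack
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / denom else 0
  adj <- function(z) {
    w <- z0 + z
    denom <- 1 - a * w
    p <- stats::pnorm(z0 + w / denom)
    bad <- !is.finite(p) | denom <= 0
    p[bad] <- ifelse(z[bad] > 0, 1, 0)
    p
  }
  ci <- stats::quantile(theta_star,
                        adj(stats::qnorm(c(alpha / 2, 1 - alpha / 2))),
                        names = FALSE)
  # p-value by interval inversion: the smallest alpha' (grid resolution 1/B)
  # at which the (1 - alpha') BCa interval excludes the null value.
  alphas <- seq_len(B - 1L) / B
  lows <- stats::quantile(theta_star, adj(stats::qnorm(alphas / 2)), names = FALSE)
  highs <- stats::quantile(theta_star, adj(stats::qnorm(1 - alphas / 2)), names = FALSE)
  excl <- which(lows > null_value | highs < null_value)
  p <- if (length(excl)) alphas[excl[1L]] else 1
  list(ci_low = ci[1L], ci_high = ci[2L], p_value = p, z0 = z0, accel = a)
}

draw_indices <- function(I, B, seed) {
  with_seed(seed, matrix(sample.int(I, I * B, replace = TRUE), nrow = B))
}

#' Subject-level BCa bootstrap for an arbitrary statistic
#'
#' Resamples subjects with replacement (I draws per replicate, sessions
#' travelling with their subject), recomputes `stat` on each replicate, and
#' returns accelerated bias-corrected percentile confidence limits together
#' with a p-value obtained by inverting the interval against `null_value`.
#'
#' @param stat Function taking a list of per-subject data (a subset, with
#'   repetition, of `data`) and returning a scalar.
#' @param data List with one element per subject; the element layout is
#'   opaque to the bootstrap and interpreted only by `stat`.
#' @param B Number of bootstrap replicates (>= 200).
#' @param alpha Two-sided interval level (0 < alpha < 1); default 0.05.
#' @param seed Optional seed; the global RNG state is left untouched.
#' @param null_value Null value for the inverted p-value (default 0).
#' @return List of class `bca_ci` with `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `z0`, `accel`, `B`, `alpha`.
#' @export
bca_bootstrap <- function(stat, data, B = 2000L, alpha = 0.05, seed = NULL,
                          null_value = 0) {
  B <- as.integer(B)
  if (is.na(B) || B < 200L) stop("`B` must be >= 200", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  I <- length(data)
  if (I < 2L) stop("need >= 2 subjects", call. = FALSE)
  theta_hat <- stat(data)
  draws <- draw_indices(I, B, seed)
  theta_star <- vapply(seq_len(B), function(b) stat(data[draws[b, ]]), 0)
  theta_jack <- vapply(seq_len(I), function(i) stat(data[-i]), 0)
  res <- bca_from_samples(theta_hat, theta_star, theta_jack, alpha, null_value)
  structure(c(list(estimate = theta_hat), res, list(B = B, alpha = alpha)),
            class = "bca_ci")
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("estimate %.4f, %d%% BCa CI [%.4f, %.4f], p = %.4g (B = %d)\n",
              x$estimate, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$p_value, x$B))
  invisible(x)
}

#' I2C2 with subject-level BCa bootstrap inference
#'
#' Identical in distribution to passing [i2c2()] through [bca_bootstrap()]
#' (same subject resampling, same seed stream), but computed from per-subject
#' sufficient statistics: per-subject sums, squared norms, within-subject
#' sums of squares and the Gram matrix of subject sum-images. Each bootstrap
#' replicate then costs O(I^2) regardless of the voxel count, which makes
#' dense voxel matrices and coverage simulations tractable.
#'
#' @inheritParams i2c2
#' @inheritParams bca_bootstrap
#' @return A `bca_ci` list (see [bca_bootstrap()]).
#' @export
i2c2_bca <- function(x, subject = NULL, B = 2000L, alpha = 0.05, seed = NULL) {
  B <- as.integer(B)
  if (is.na(B) || B < 200L) stop("`B` must be >= 200", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  d <- as_record_values(x, subject)
  X <- d$values
  grp <- factor(d$subject, levels = unique(d$subject))
  I <- nlevels(grp)
  if (I < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (nrow(X) <= I) stop("need >= 1 subject with >= 2 records", call. = FALSE)

  n_i <- tabulate(grp, I)                    # sessions per subject
  S <- rowsum(X, grp)                        # subject sum images (I x V)
  q_i <- as.numeric(rowsum(rowSums(X^2), grp))
  ssw_i <- q_i - rowSums(S^2) / n_i          # within-subject sums of squares
  G <- S %*% t(S)                            # Gram matrix of sum images

  # lambda for a multiset of subjects given per-subject multiplicities c:
  # Tw = c'ssw / (N* - I), Tt = (c'q - (c'Gc)/N*) / (N* - 1), N* = c'n.
  lambda_from_counts <- function(Cm) {
    Nst <- drop(Cm %*% n_i)
    Tw <- drop(Cm %*% ssw_i) / (Nst - I)
    quad <- rowSums((Cm %*% G) * Cm)
    Tt <- (drop(Cm %*% q_i) - quad / Nst) / (Nst - 1)
    lam <- 1 - Tw / Tt
    lam[Tt <= 0] <- 1
    lam
  }
  theta_hat <- lambda_from_counts(matrix(1, 1L, I))

  draws <- draw_indices(I, B, seed)
  Cm <- matrix(0L, B, I)
  for (b in seq_len(B)) Cm[b, ] <- tabulate(draws[b, ], nbins = I)
  theta_star <- lambda_from_counts(Cm)

  # Leave-one-subject-out jackknife (I - 1 subjects).
  g1 <- rowSums(G)
  theta_jack <- vapply(seq_len(I), function(i) {
    Nst <- sum(n_i) - n_i[i]
    Tw <- (sum(ssw_i) - ssw_i[i]) / (Nst - (I - 1L))
    quad <- sum(G) - 2 * g1[i] + G[i, i]
    Tt <- (sum(q_i) - q_i[i] - quad / Nst) / (Nst - 1)
    if (Tt <= 0) 1 else 1 - Tw / Tt
  }, 0)

  res <- bca_from_samples(theta_hat, theta_star, theta_jack, alpha,
                          null_value = 0)
  structure(c(list(estimate = theta_hat), res, list(B = B, alpha = alpha)),
            class = "bca_ci")
}
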