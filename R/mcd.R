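#' Minimum covariance determinant location and scatter
#'
#' Robust multivariate location/scatter estimate: the mean and covariance of
#' the size-`h` subset of rows (`h = floor(alpha * n)`) whose classical
#' covariance has the smallest determinant. For small problems
#' (`choose(n, h) <= exact_limit`) every subset is enumerated, so the
#' estimate is exact; otherwise a seeded concentration-step (C-step) search
#' is used: random elemental starts are refined by repeatedly re-fitting on
#' the `h` observations closest in Mahalanobis distance, which can only
#' decrease the determinant, and the best of several starts is kept. The
#' search is deterministic for a fixed `seed`.
#'
#' Delta matrices of normalized profiles are rank-deficient (rows sum to 0),
#' so determinants and Mahalanobis distances are stabilized with a small
#' fixed ridge, `1e-9 * mean(diag(cov(x)))`, added to every candidate
#' scatter. The raw subset covariance is multiplied by the standard
#' consistency factor `alpha' / pchisq(qchisq(alpha', r), r + 2)` (with
#' `alpha' = h/n` and `r` the data rank) so that squared robust distances of
#' Gaussian data follow the reference chi-square distribution.
#'
#' @param x Numeric matrix (n rows, d columns), n > d.
#' @param alpha Fraction of rows used for the determinant subset
#'   (default 0.9).
#' @param seed Integer seed for the subset search.
#' @param nstarts Number of random elemental starts (large-n path).
#' @param exact_limit Maximum number of subsets for exhaustive enumeration.
#' @return A list of class `mcd_fit`: `center`, `cov_raw` (unscaled subset
#'   covariance), `cov` (consistency-scaled), `factor`, `best` (row indices
#'   of the optimal subset), `h`, `ridge`, `rank`.
#' @export
mcd_estimate <- function(x, alpha = 0.9, seed = 1L, nstarts = 60L,
                         exact_limit = 50000) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  h <- floor(alpha * n)
  if (h <= d + 1) {
    abort(sprintf("Too few rows (n = %d) for a %d-dimensional MCD fit.", n, d))
  }
  ridge <- 1e-9 * mean(diag(stats::cov(x)))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
  reg <- diag(ridge, d)

  subset_det <- function(idx) {
    s <- stats::cov(x[idx, , drop = FALSE]) + reg
    det(s)
  }

  n_subsets <- suppressWarnings(choose(n, h))
  if (is.finite(n_subsets) && n_subsets <= exact_limit) {
    subs <- combn(n, h)
    dets <- apply(subs, 2, subset_det)
    best <- subs[, which.min(dets)]
  } else {
    best <- .mcd_csteps(x, h, reg, seed = seed, nstarts = nstarts)
  }

  center <- colMeans(x[best, , drop = FALSE])
  cov_raw <- stats::cov(x[best, , drop = FALSE])
  rank <- max(1L, sum(
    eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values >
      1e-10 * max(1e-300, mean(diag(stats::cov(x))))
  ))
  a <- h / n
  cf <- a / pchisq(qchisq(a, rank), rank + 2)
  structure(
    list(
      center = center, cov_raw = cov_raw, cov = cov_raw * cf, factor = cf,
      best = sort(best), h = h, ridge = ridge, rank = rank
    ),
    class = "mcd_fit"
  )
}

# Seeded FAST-MCD style search: many elemental starts, 2 C-steps each,
# full convergence for the most promising candidates.
.mcd_csteps <- function(x, h, reg, seed, nstarts, keep = 10L, max_iter = 50L) {
  n <- nrow(x)
  d <- ncol(x)
  cstep <- function(idx, iters) {
    for (i in seq_len(iters)) {
      mu <- colMeans(x[idx, , drop = FALSE])
      s <- stats::cov(x[idx, , drop = FALSE]) + reg
      d2 <- mahalanobis(x, mu, s)
      new_idx <- order(d2)[seq_len(h)]
      if (identical(sort(new_idx), sort(idx))) break
      idx <- new_idx
    }
    list(idx = idx, det = det(stats::cov(x[idx, , drop = FALSE]) + reg))
  }
  withr::with_seed(seed, {
    cands <- lapply(seq_len(nstarts), function(k) {
      start <- sample.int(n, min(n, d + 1L))
      mu <- colMeans(x[start, , drop = FALSE])
      s <- stats::cov(x[start, , drop = FALSE]) + reg
      d2 <- mahalanobis(x, mu, s)
      cstep(order(d2)[seq_len(h)], 2L)
    })
    dets <- vapply(cands, `[[`, numeric(1), "det")
    top <- order(dets)[seq_len(min(keep, length(cands)))]
    refined <- lapply(cands[top], function(c0) cstep(c0$idx, max_iter))
    dets2 <- vapply(refined, `[[`, numeric(1), "det")
    refined[[which.min(dets2)]]$idx
  })
}

#' Squared robust Mahalanobis distances from an MCD fit
#'
#' @param fit An `mcd_fit`.
#' @param x The data matrix.
#' @param scaled Use the consistency-scaled scatter (default) or the raw
#'   subset covariance.
#' @return Numeric vector of squared distances.
#' @export
mcd_distances <- function(fit, x, scaled = TRUE) {
  s <- (if (scaled) fit$cov else fit$cov_raw) + diag(fit$ridge, ncol(x))
  mahalanobis(as.matrix(x), fit$center, s)
}
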