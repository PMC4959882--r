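# Independent reference implementations used as oracles. These are written
# against the definitions directly (enumeration / sort-based step-up) and
# must stay independent of the package internals they check.

# Exhaustive MCD: enumerate every h-subset, pick the one whose classical
# covariance (plus the documented stabilizing ridge) has minimal determinant.
oracle_mcd <- function(x, alpha = 0.9) {
  n <- nrow(x)
  d <- ncol(x)
  h <- floor(alpha * n)
  ridge <- 1e-9 * mean(diag(stats::cov(x)))
  subs <- utils::combn(n, h)
  dets <- apply(subs, 2, function(idx) {
    det(stats::cov(x[idx, , drop = FALSE]) + diag(ridge, d))
  })
  best <- subs[, which.min(dets)]
  center <- colMeans(x[best, , drop = FALSE])
  cov_raw <- stats::cov(x[best, , drop = FALSE])
  dist <- stats::mahalanobis(x, center, cov_raw + diag(ridge, d))
  list(best = sort(best), center = center, cov_raw = cov_raw, dist = dist)
}

# Direct Benjamini-Hochberg step-up: sort p ascending, q_(i) = min_{j >= i}
# p_(j) * N / j, mapped back to the original order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(ps * n / seq_len(n), 1)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Closed-form proteomic ruler for a single intensity column.
oracle_ruler_copies <- function(intensity, mw_kda, is_histone, ploidy = 3,
                                haploid_genome_pg = 3.1) {
  dna_g <- haploid_genome_pg * 1e-12 * ploidy
  total_mass <- dna_g * sum(intensity) / sum(intensity[is_histone])
  (intensity / sum(intensity)) * total_mass * 6.02214076e23 / (mw_kda * 1000)
}

# Mean silhouette width for a 2-class labelling of 2-d points.
oracle_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(
      unique(labels[!own]),
      function(l) mean(d[i, labels == l]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
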