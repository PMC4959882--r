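#' Magnitude-of-translocation (M) scores for one delta matrix
#'
#' Proteins that do not move have delta profiles reflecting only Gaussian
#' experimental noise, so the delta matrix is approximately multivariate
#' normal except for genuine movers. Outliers are detected by the squared
#' Mahalanobis distance to a robust centre: location and scatter are
#' estimated by the minimum covariance determinant on `mcd_fraction` of the
#' rows, distances are converted to chi-square upper-tail p-values with `df`
#' degrees of freedom, Benjamini-Hochberg adjusted across all proteins of
#' the matrix, and reported as `M = -log10(Q)`.
#'
#' Because normalized-profile deltas sum to zero, the 5-dimensional scatter
#' is singular up to noise; distances are stabilized by a small ridge inside
#' [mcd_estimate()]. The default `df = 5` matches the published procedure
#' (one degree per fraction); `df = 4` treats the delta as living in its
#' true 4-dimensional subspace and is slightly less conservative.
#'
#' @param delta A delta tibble from [compute_delta()].
#' @param scheme A [fraction_scheme()].
#' @param mcd_fraction Fraction of rows for the MCD subset (default 0.9).
#' @param df Chi-square degrees of freedom (5, or 4 for the subspace view).
#' @param seed Seed for the MCD subset search.
#' @return Tibble `protein_id`, `distance`, `p_value`, `q_value`, `m`.
#' @export
m_scores <- function(delta, scheme = fraction_scheme(), mcd_fraction = 0.9,
                     df = 5, seed = 1L) {
  x <- delta_matrix(delta, scheme)
  n <- nrow(x)
  if (n < 4 * ncol(x)) {
    abort(sprintf("Too few proteins (n = %d) for a stable MCD fit.", n))
  }
  if (n < 20 * ncol(x)) {
    warn(sprintf(
      "Only %d proteins for a %d-dimensional MCD fit; M scores may be unstable.",
      n, ncol(x)
    ))
  }
  fit <- mcd_estimate(x, alpha = mcd_fraction, seed = seed)
  d2 <- mcd_distances(fit, x)
  p <- pchisq(d2, df = df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tibble(
    protein_id = delta$protein_id, distance = unname(d2),
    p_value = unname(p), q_value = unname(q), m = -log10(unname(q))
  )
}

#' Reproducibility-of-translocation (R) scores
#'
#' A genuinely translocating protein shifts in the same direction in every
#' replicate, so its delta profiles from different replicate pairs are
#' highly correlated. For every protein common to all supplied delta
#' matrices, the Pearson correlation of its 5-element delta profiles is
#' computed for every pair of replicates.
#'
#' A zero-variance delta profile has no defined correlation; the value is
#' returned as `NA`, which fails any positive score threshold downstream.
#'
#' @param deltas List of 2 or more delta tibbles (one per replicate pair).
#' @param scheme A [fraction_scheme()].
#' @return Tibble `protein_id`, `pair` (e.g. `"1:2"`), `r`.
#' @export
r_scores <- function(deltas, scheme = fraction_scheme()) {
  if (length(deltas) < 2) abort("Need at least 2 delta matrices for R scores.")
  common <- Reduce(intersect, lapply(deltas, function(d) d$protein_id))
  if (length(common) == 0) abort("Delta matrices share no proteins.")
  mats <- lapply(deltas, function(d) delta_matrix(d, scheme)[common, , drop = FALSE])
  combos <- combn(length(deltas), 2)
  out <- lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]
    j <- combos[2, k]
    a <- mats[[i]]
    b <- mats[[j]]
    ac <- a - rowMeans(a)
    bc <- b - rowMeans(b)
    num <- rowSums(ac * bc)
    den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    tibble(
      protein_id = common, pair = paste0(i, ":", j),
      r = unname(r)
    )
  })
  bind_rows(out)
}

#' Combine replicate M and R scores into MR scores
#'
#' Stringent mode keeps, per protein, the lowest M and lowest R across
#' replicates (a hit must score in every replicate); sensitive mode keeps
#' the medians. A duplicate experiment yields two M scores and one R score,
#' which are combined the same way.
#'
#' @param m_tbl Long tibble of per-pair M scores: `protein_id`, `pair`, `m`
#'   (e.g. bound rows of [m_scores()] results with a `pair` column).
#' @param r_tbl Long tibble from [r_scores()].
#' @param mode `"stringent"` or `"sensitive"`.
#' @return An `mr_scores` tibble: `protein_id`, `m_combined`, `r_combined`,
#'   plus per-pair `m_*` and `r_*` columns. `NA` correlations propagate to
#'   `r_combined` and fail positive thresholds.
#' @export
combine_mr <- function(m_tbl, r_tbl, mode = c("stringent", "sensitive")) {
  mode <- match.arg(mode)
  agg <- if (mode == "stringent") {
    function(v) if (anyNA(v)) NA_real_ else min(v)
  } else {
    function(v) if (anyNA(v)) NA_real_ else median(v)
  }
  m_wide <- tidyr::pivot_wider(
    select(m_tbl, "protein_id", "pair", "m"),
    names_from = "pair", values_from = "m", names_prefix = "m_"
  )
  r_wide <- tidyr::pivot_wider(
    select(r_tbl, "protein_id", "pair", "r"),
    names_from = "pair", values_from = "r", names_prefix = "r_"
  )
  mc <- m_tbl |>
    group_by(.data$protein_id) |>
    summarise(m_combined = agg(.data$m), .groups = "drop")
  rc <- r_tbl |>
    group_by(.data$protein_id) |>
    summarise(r_combined = agg(.data$r), .groups = "drop")
  out <- mc |>
    inner_join(rc, by = "protein_id") |>
    left_join(m_wide, by = "protein_id") |>
    left_join(r_wide, by = "protein_id")
  attr(out, "mode") <- mode
  class(out) <- c("mr_scores", class(out))
  out
}
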