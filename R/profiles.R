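#' Convert raw H/L ratio profiles to normalized fractionation profiles
#'
#' SILAC H/L ratios are inverted to L/H (enrichment of each pellet fraction
#' over the heavy reference), weighted by the relative protein yield of each
#' fraction, and row-normalized. The result is a distribution profile: for
#' each protein the proportion of its total pelleted material recovered in
#' each of the five fractions, summing to 1.
#'
#' For row r and fraction j with yield weight w_j,
#' `p_rj = (w_j / HL_rj) / sum_k (w_k / HL_rk)`.
#'
#' @param raw Profile tibble of raw H/L ratios (`ratio_*` columns), e.g.
#'   from [filter_profile_group()].
#' @param scheme A [fraction_scheme()] supplying the yield weights.
#' @return A profile tibble of the same shape with `kind = "normalized"`;
#'   every row of the `ratio_*` columns sums to 1.
#' @export
#'
#' @examples
#' sc <- fraction_scheme()
#' raw <- tibble::tibble(
#'   protein_id = "P1",
#'   ratio_3K = 2, `ratio_5.4K` = 1, `ratio_12.2K` = 0.5,
#'   ratio_24K = 1, `ratio_78.4K` = 1
#' )
#' normalize_map(raw, sc)
normalize_map <- function(raw, scheme = fraction_scheme()) {
  m <- profile_matrix(raw, scheme)
  bad <- which(!(is.finite(m) & m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-positive or missing ratio for protein %s in fraction %s.",
      raw$protein_id[bad[1, 1]], scheme$profile_fractions[bad[1, 2]]
    ))
  }
  w <- scheme$profile_yields
  inv <- sweep(1 / m, 2, w, `*`)
  p <- inv / rowSums(inv)
  out <- raw
  out[, profile_cols(scheme)] <- as_tibble(as.data.frame(p))
  attr(out, "kind") <- "normalized"
  out
}

#' Delta profiles between a treated and a control map
#'
#' Subtracts normalized profiles fraction by fraction (treated minus
#' control), restricted to the proteins present in both maps. A protein
#' that did not move has a delta profile near zero; every delta row sums to
#' 0 because both inputs sum to 1.
#'
#' @param control,treated Normalized profile tibbles.
#' @param scheme A [fraction_scheme()].
#' @param pair_id Optional label for the replicate pair.
#' @return A delta tibble: `protein_id` plus five `delta_*` columns.
#' @export
compute_delta <- function(control, treated, scheme = fraction_scheme(),
                          pair_id = NULL) {
  common <- intersect(control$protein_id, treated$protein_id)
  if (length(common) == 0) {
    abort("Control and treated maps share no proteins.")
  }
  mc <- profile_matrix(control, scheme)[common, , drop = FALSE]
  mt <- profile_matrix(treated, scheme)[common, , drop = FALSE]
  d <- mt - mc
  out <- tibble(protein_id = common)
  dc <- as_tibble(as.data.frame(d))
  names(dc) <- paste0("delta_", scheme$profile_fractions)
  out <- bind_cols(out, dc)
  attr(out, "pair_id") <- pair_id
  out
}

# n x 5 matrix from a delta tibble
delta_matrix <- function(delta, scheme = fraction_scheme()) {
  cols <- paste0("delta_", scheme$profile_fractions)
  m <- as.matrix(delta[, cols])
  rownames(m) <- delta$protein_id
  m
}

#' Concordance between two maps' compartment predictions
#'
#' The percentage of proteins, present in both prediction sets with a
#' prediction score of at least `min_score` in both, whose top compartment
#' predictions agree.
#'
#' @param pred_a,pred_b Tibbles with `protein_id`, `top_prediction` and a
#'   score column (`top_score` by default).
#' @param min_score Minimum score required in both maps.
#' @param score_col Name of the score column.
#' @return A one-row tibble: `n_common`, `n_identical`, `concordance`
#'   (percent). If no protein passes the threshold in both maps the
#'   concordance is `NA` and a warning is raised.
#' @export
map_concordance <- function(pred_a, pred_b, min_score = -Inf,
                            score_col = "top_score") {
  joined <- inner_join(
    select(
      pred_a, "protein_id",
      pred_a = "top_prediction", score_a = tidyselect::all_of(score_col)
    ),
    select(
      pred_b, "protein_id",
      pred_b = "top_prediction", score_b = tidyselect::all_of(score_col)
    ),
    by = "protein_id"
  )
  joined <- filter(joined, .data$score_a >= min_score, .data$score_b >= min_score)
  if (nrow(joined) == 0) {
    warn("No proteins shared above the score threshold; concordance undefined.")
    return(tibble(n_common = 0L, n_identical = 0L, concordance = NA_real_))
  }
  n_id <- sum(joined$pred_a == joined$pred_b)
  tibble(
    n_common = nrow(joined), n_identical = n_id,
    concordance = 100 * n_id / nrow(joined)
  )
}

#' Profile neighbourhood of a query protein
#'
#' Ranks all proteins of a map by squared Euclidean distance between their
#' fractionation profiles and the query's. Proteins at small distances
#' co-fractionate with the query; members of stable complexes typically
#' appear at near-zero distances.
#'
#' @param matrix_tbl A profile tibble (normalized or raw).
#' @param query A `protein_id` present in the map.
#' @param scheme A [fraction_scheme()].
#' @return A tibble `protein_id`, `sq_distance`, sorted ascending; the query
#'   itself is first with distance 0.
#' @export
neighbourhood <- function(matrix_tbl, query, scheme = fraction_scheme()) {
  m <- profile_matrix(matrix_tbl, scheme)
  if (!query %in% rownames(m)) {
    abort(sprintf("Query protein '%s' is not in the map.", query))
  }
  q <- m[query, ]
  d2 <- colSums((t(m) - q)^2)
  out <- tibble(protein_id = rownames(m), sq_distance = unname(d2))
  arrange(out, .data$sq_distance, .data$protein_id)
}

#' Project one or more maps into principal-component space
#'
#' Concatenates the ratio columns of the supplied maps on their common
#' proteins (30 columns for 6 maps), log-transforms the inverted (L/H)
#' enrichment ratios, scales every column to unit variance and runs PCA.
#' The sign of each component is fixed so the loading of the first data
#' column is non-negative, making plots reproducible across runs. The best
#' visual separation of organellar clusters is usually PC1 vs PC3.
#'
#' @param maps A profile tibble or list of profile tibbles of raw H/L
#'   ratios.
#' @param scheme A [fraction_scheme()].
#' @param n_components Number of components to return.
#' @return An object of class `map_pca`: list with `scores` (tibble:
#'   `protein_id`, `PC1`, ...), `explained_variance` and the `prcomp` fit.
#' @export
pca_project <- function(maps, scheme = fraction_scheme(), n_components = 3) {
  if (is.data.frame(maps)) maps <- list(maps)
  common <- Reduce(intersect, lapply(maps, function(m) m$protein_id))
  if (length(common) < 2) abort("Need at least 2 common proteins for PCA.")
  blocks <- lapply(seq_along(maps), function(i) {
    m <- profile_matrix(maps[[i]], scheme)[common, , drop = FALSE]
    if (any(!is.finite(m) | m <= 0)) {
      abort("PCA input ratios must be finite and positive.")
    }
    log(1 / m) # L/H enrichment, natural log
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- paste0(
    "m", rep(seq_along(maps), each = 5), "_",
    rep(scheme$profile_fractions, length(maps))
  )
  sds <- apply(x, 2, sd)
  const <- sds < 1e-12
  if (any(const)) {
    warn(paste0(
      "Dropping constant column(s) after log transform: ",
      paste(colnames(x)[const], collapse = ", ")
    ))
    x <- x[, !const, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(fit$x))
  # deterministic sign: first feature's loading non-negative per component
  for (j in seq_len(k)) {
    if (fit$rotation[1, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(as.data.frame(fit$x[, seq_len(k), drop = FALSE]))
  scores <- bind_cols(tibble(protein_id = common), scores)
  structure(
    list(scores = scores, explained_variance = ev[seq_len(k)], fit = fit),
    class = "map_pca"
  )
}

#' @export
print.map_pca <- function(x, ...) {
  cat("<map_pca>", nrow(x$scores), "proteins,",
    length(x$explained_variance), "components\n")
  cat("  explained variance:",
    paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}
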