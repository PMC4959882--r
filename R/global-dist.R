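#' Global nuclear/organellar/cytosolic distribution profiles
#'
#' Converts raw N/O/C fraction intensities (Group 2 data) into per-protein
#' global distribution profiles. Each fraction column is first scaled to the
#' same total intensity (removing run-to-run loading differences), then
#' weighted by the fraction's relative protein yield; the weighted
#' intensities are summed into a whole-cell relative intensity, and divided
#' by it to give shares over organellar, nuclear and cytosolic pools that
#' sum to 1. A global class is assigned to each profile with
#' [assign_global_class()].
#'
#' @param intensities Tibble with `protein_id` and `intensity_<label>`
#'   columns for the three global fractions (e.g. from
#'   [filter_intensity_group()]).
#' @param scheme A [fraction_scheme()] supplying the global yield weights.
#' @return Tibble `protein_id`, `share_o`, `share_n`, `share_c`,
#'   `whole_cell`, `global_class`. Proteins with zero total intensity are
#'   dropped with a warning.
#' @export
onc_profiles <- function(intensities, scheme = fraction_scheme()) {
  gf <- scheme$global_fractions
  icols <- paste0("intensity_", gf)
  m <- as.matrix(intensities[, icols])
  m[is.na(m)] <- 0
  totals <- colSums(m)
  if (any(totals <= 0)) abort("A global fraction has zero total intensity.")
  scaled <- sweep(m, 2, mean(totals) / totals, `*`)
  weighted <- sweep(scaled, 2, scheme$global_yields[gf], `*`)
  whole <- rowSums(weighted)
  zero <- whole <= 0
  if (any(zero)) {
    warn(sprintf("%d protein(s) with zero total intensity dropped.", sum(zero)))
  }
  shares <- weighted[!zero, , drop = FALSE] / whole[!zero]
  colnames(shares) <- paste0("share_", tolower(gf))
  out <- bind_cols(
    tibble(protein_id = intensities$protein_id[!zero]),
    as_tibble(as.data.frame(shares)),
    tibble(whole_cell = whole[!zero])
  )
  out$global_class <- assign_global_class(
    out$share_o, out$share_n, out$share_c
  )
  out
}

#' Assign a global distribution class from O/N/C shares
#'
#' Classes are assigned by the first matching rule, in order: mostly
#' nuclear `N` (n >= 0.85); mostly cytosolic `C` (c >= 0.85); mostly
#' organellar `O` (c < 0.15 and o > 0.3); organellar/cytosolic `O/C`
#' (n < 0.4, c > 0.15, o > 0.15); nuclear/cytosolic `N/C` (n > 0.15,
#' c >= 0.15, o < 0.1); otherwise broad `B`. The function is total: every
#' valid share triple receives exactly one class.
#'
#' @param o,n,c Numeric vectors of organellar, nuclear and cytosolic shares
#'   (each triple summing to 1).
#' @return Character vector of class labels.
#' @export
#'
#' @examples
#' assign_global_class(0.05, 0.90, 0.05) # "N"
#' assign_global_class(0.45, 0.50, 0.05) # "O"
assign_global_class <- function(o, n, c) {
  dplyr::case_when(
    n >= 0.85 ~ "N",
    c >= 0.85 ~ "C",
    c < 0.15 & o > 0.3 ~ "O",
    n < 0.4 & c > 0.15 & o > 0.15 ~ "O/C",
    n > 0.15 & c >= 0.15 & o < 0.1 ~ "N/C",
    TRUE ~ "B"
  )
}

#' Organellar leakage from lumenal marker proteins
#'
#' Lumenal proteins of an intact organelle should have no cytosolic pool;
#' their cytosolic shares therefore measure lysis-induced leakage. Shares
#' below 1% indicate membrane-attached (non-leakable) proteins, shares
#' above 20% usually genuine cytosolic pools (e.g. splice variants), so the
#' reported leakage is the mean cytosolic share of the 1-20% band only
#' (band edges inclusive).
#'
#' @param onc ONC profile tibble from [onc_profiles()].
#' @param lumenal_markers Tibble `protein_id`, `organelle`.
#' @return Per-organelle tibble: band counts `n_below` (< 1%), `n_band`
#'   (1-20%), `n_above` (> 20%), `leakage_pct` (mean of the middle band, in
#'   percent; 0 with `flagged = TRUE` when the band is empty).
#' @export
#'
#' @examples
#' onc <- tibble::tibble(
#'   protein_id = paste0("P", 1:4),
#'   share_c = c(0.005, 0.05, 0.10, 0.50)
#' )
#' mk <- tibble::tibble(protein_id = paste0("P", 1:4), organelle = "ER")
#' leakage_stats(onc, mk) # band counts 1/2/1, leakage 7.5%
leakage_stats <- function(onc, lumenal_markers) {
  if (nrow(lumenal_markers) == 0) abort("Marker list is empty.")
  joined <- inner_join(lumenal_markers, onc, by = "protein_id")
  joined |>
    group_by(organelle = .data$organelle) |>
    summarise(
      n_below = sum(.data$share_c < 0.01),
      n_band = sum(.data$share_c >= 0.01 & .data$share_c <= 0.20),
      n_above = sum(.data$share_c > 0.20),
      leakage_pct = if (any(.data$share_c >= 0.01 & .data$share_c <= 0.20)) {
        100 * mean(.data$share_c[.data$share_c >= 0.01 & .data$share_c <= 0.20])
      } else {
        0
      },
      flagged = !any(.data$share_c >= 0.01 & .data$share_c <= 0.20),
      .groups = "drop"
    )
}

#' Compare LFQ pools between conditions (global change volcano test)
#'
#' Tests, separately for each global fraction, whether a protein's pool
#' changed between conditions. LFQ intensities are log2-transformed and
#' filtered for at least 3 valid values in at least one group; remaining
#' missing values are imputed from a normal distribution positioned in each
#' sample's low-intensity tail (mean shifted down `downshift` column SDs,
#' width `width` column SDs; observed values are never overwritten). A
#' two-sided two-sample Student t-test (pooled variance by default) is
#' applied per protein. A change is significant only if all three filters
#' pass: `|log2 difference| > fc_cutoff`, the protein holds at least
#' `pool_min` of its total pool in that fraction before or after treatment,
#' and `-log10 p` exceeds the fraction-specific cut-off (defaults from a
#' mock-experiment calibration: cytosolic 2.0, organellar 3.1,
#' nuclear 2.6).
#'
#' @param lfq Long tibble: `protein_id`, `fraction` (matching the scheme's
#'   global labels), `condition` (`"control"`/`"treated"`), `replicate`,
#'   `lfq` (raw intensity, `NA` when missing).
#' @param onc_before,onc_after ONC profile tibbles supplying pool shares
#'   before/after treatment (`onc_after` defaults to `onc_before`).
#' @param scheme A [fraction_scheme()].
#' @param p_cutoffs Named vector of `-log10 p` cut-offs per fraction label.
#' @param fc_cutoff Minimum absolute log2 fold change (default 1).
#' @param pool_min Minimum pool share before or after (default 0.10).
#' @param downshift,width Imputation parameters in column-SD units.
#' @param seed Seed for the imputation draws.
#' @param var_equal Pooled-variance Student t-test (`TRUE`, default) or
#'   Welch.
#' @return A `global_change` tibble: per protein and fraction, group means,
#'   `log2_diff`, `t`, `p_value`, `neg_log10_p`, `share_before`,
#'   `share_after`, `n_imputed`, `significant`.
#' @export
lfq_compare <- function(lfq, onc_before, onc_after = NULL,
                        scheme = fraction_scheme(),
                        p_cutoffs = c(C = 2.0, O = 3.1, N = 2.6),
                        fc_cutoff = 1, pool_min = 0.10,
                        downshift = 2, width = 0.3, seed = 1L,
                        var_equal = TRUE) {
  onc_after <- onc_after %||% onc_before
  share_col <- function(onc, frac) {
    setNames(onc[[paste0("share_", tolower(frac))]], onc$protein_id)
  }
  res <- list()
  for (frac in scheme$global_fractions) {
    sub <- filter(lfq, .data$fraction == frac)
    if (nrow(sub) == 0) next
    wide <- tidyr::pivot_wider(
      sub,
      id_cols = "protein_id",
      names_from = c("condition", "replicate"), values_from = "lfq"
    )
    cn <- names(wide)[-1]
    ctrl_cols <- grep("^control", cn, value = TRUE)
    trt_cols <- grep("^treated", cn, value = TRUE)
    if (length(ctrl_cols) < 3 || length(trt_cols) < 3) {
      abort("Each condition needs at least 3 replicates per fraction.")
    }
    x <- log2(as.matrix(wide[, c(ctrl_cols, trt_cols)]))
    valid_ctrl <- rowSums(is.finite(x[, ctrl_cols, drop = FALSE]))
    valid_trt <- rowSums(is.finite(x[, trt_cols, drop = FALSE]))
    keep <- valid_ctrl >= 3 | valid_trt >= 3
    x <- x[keep, , drop = FALSE]
    ids <- wide$protein_id[keep]
    n_imputed <- rowSums(!is.finite(x))
    withr::with_seed(seed + match(frac, scheme$global_fractions), {
      for (j in seq_len(ncol(x))) {
        obs <- x[, j][is.finite(x[, j])]
        nmiss <- sum(!is.finite(x[, j]))
        if (nmiss > 0) {
          mu <- mean(obs) - downshift * sd(obs)
          x[!is.finite(x[, j]), j] <- rnorm(nmiss, mu, width * sd(obs))
        }
      }
    })
    mc <- rowMeans(x[, ctrl_cols, drop = FALSE])
    mt <- rowMeans(x[, trt_cols, drop = FALSE])
    stats_tbl <- t(apply(x, 1, function(row) {
      tryCatch(
        {
          tt <- t.test(row[seq_along(trt_cols) + length(ctrl_cols)],
            row[seq_along(ctrl_cols)],
            var.equal = var_equal
          )
          c(t = unname(tt$statistic), p = tt$p.value)
        },
        # constant data: no evidence of change
        error = function(e) c(t = NA_real_, p = NA_real_)
      )
    }))
    sb <- share_col(onc_before, frac)[ids]
    sa <- share_col(onc_after, frac)[ids]
    cut <- p_cutoffs[[frac]]
    out <- tibble(
      protein_id = ids, fraction = frac,
      mean_control = unname(mc), mean_treated = unname(mt),
      log2_diff = unname(mt - mc),
      t = unname(stats_tbl[, "t"]), p_value = unname(stats_tbl[, "p"]),
      neg_log10_p = -log10(unname(stats_tbl[, "p"])),
      share_before = unname(sb), share_after = unname(sa),
      n_imputed = unname(n_imputed)
    )
    pool_ok <- pmax(out$share_before, out$share_after, na.rm = TRUE)
    pool_ok[is.na(out$share_before) & is.na(out$share_after)] <- NA
    out$significant <- !is.na(out$p_value) &
      abs(out$log2_diff) > fc_cutoff &
      !is.na(pool_ok) & pool_ok >= pool_min &
      out$neg_log10_p > cut
    res[[frac]] <- out
  }
  out <- bind_rows(res)
  class(out) <- c("global_change", class(out))
  out
}
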