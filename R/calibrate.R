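#' Depth-scaled expected false positives and FDR
#'
#' When the mock experiment and the real experiment have different depths
#' (numbers of proteins tested), the mock hit count is scaled by the depth
#' ratio before being interpreted as the expected number of false positives
#' among the experiment's hits.
#'
#' @param mock_hits Hits observed in the mock experiment at the chosen
#'   cut-offs.
#' @param mock_depth,experiment_depth Numbers of proteins in mock and real
#'   experiment.
#' @param experiment_hits Hits observed in the real experiment.
#' @return A one-row tibble: `expected_fp`, `fdr` (fraction). With zero
#'   experiment hits but positive expected false positives the FDR is
#'   undefined (`NA` with a warning).
#' @export
#'
#' @examples
#' scale_fdr(3, 3766, 2237, 18) # 1.8 expected FP, FDR 0.10
scale_fdr <- function(mock_hits, mock_depth, experiment_depth, experiment_hits) {
  if (mock_depth <= 0 || experiment_depth <= 0) abort("Depths must be positive.")
  if (mock_hits < 0 || experiment_hits < 0) abort("Hit counts must be >= 0.")
  expected_fp <- mock_hits * experiment_depth / mock_depth
  fdr <- if (experiment_hits > 0) {
    expected_fp / experiment_hits
  } else if (expected_fp > 0) {
    warn("No experiment hits but positive expected false positives; FDR undefined.")
    NA_real_
  } else {
    0
  }
  tibble(expected_fp = expected_fp, fdr = fdr)
}

#' Calibrate MR cut-offs on a mock experiment
#'
#' A mock experiment (replicate maps of a single condition, split into
#' pseudo-control and pseudo-treated) contains no true movers, so any
#' protein in its upper-right MR quadrant is a false positive. Cut-offs are
#' chosen on a grid: for `target_fdr = 0`, the admissible pairs leave zero
#' mock proteins with `M >= m_cut & R >= r_cut`; for `target_fdr > 0`, the
#' depth-scaled expected mock hits divided by the experiment hits must not
#' exceed the target. Among admissible pairs the one maximizing experiment
#' hits is chosen, ties resolved toward lower M, then lower R.
#'
#' @param mock An `mr_scores` tibble from the mock comparison.
#' @param experiment An `mr_scores` tibble from the real comparison.
#' @param target_fdr Target false discovery rate (fraction; default 0).
#' @param m_grid,r_grid Candidate cut-off grids.
#' @return A list of class `mr_calibration`: `m_cut`, `r_cut`, `fdr`,
#'   `expected_fp`, `mock_hits`, `experiment_hits`, `mock_depth`,
#'   `experiment_depth`.
#' @export
calibrate_cutoffs <- function(mock, experiment, target_fdr = 0,
                              m_grid = seq(0, 5, by = 0.1),
                              r_grid = seq(0, 1, by = 0.05)) {
  hits_at <- function(mr, m_cut, r_cut) {
    sum(!is.na(mr$m_combined) & !is.na(mr$r_combined) &
      mr$m_combined >= m_cut & mr$r_combined >= r_cut)
  }
  grid <- tidyr::expand_grid(m_cut = m_grid, r_cut = r_grid)
  grid$mock_hits <- purrr::map2_dbl(
    grid$m_cut, grid$r_cut,
    function(m, r) hits_at(mock, m, r)
  )
  grid$experiment_hits <- purrr::map2_dbl(
    grid$m_cut, grid$r_cut,
    function(m, r) hits_at(experiment, m, r)
  )
  md <- nrow(mock)
  ed <- nrow(experiment)
  grid$expected_fp <- grid$mock_hits * ed / md
  grid$fdr <- ifelse(grid$experiment_hits > 0,
    grid$expected_fp / grid$experiment_hits,
    ifelse(grid$expected_fp > 0, NA_real_, 0)
  )
  admissible <- if (target_fdr == 0) {
    grid$mock_hits == 0
  } else {
    !is.na(grid$fdr) & grid$fdr <= target_fdr
  }
  if (!any(admissible)) {
    best <- min(grid$fdr, na.rm = TRUE)
    abort(sprintf(
      "Target FDR %.3f unattainable on the grid; best achievable is %.3f.",
      target_fdr, best
    ))
  }
  cand <- grid[admissible, ]
  cand <- arrange(cand, dplyr::desc(.data$experiment_hits), .data$m_cut, .data$r_cut)
  sel <- cand[1, ]
  structure(
    list(
      m_cut = sel$m_cut, r_cut = sel$r_cut, fdr = sel$fdr,
      expected_fp = sel$expected_fp, mock_hits = sel$mock_hits,
      experiment_hits = sel$experiment_hits,
      mock_depth = md, experiment_depth = ed, grid = grid
    ),
    class = "mr_calibration"
  )
}

#' @export
print.mr_calibration <- function(x, ...) {
  cat(sprintf(
    "<mr_calibration> M >= %.2f & R >= %.2f: %d experiment hits, %.2f expected FP (FDR %.1f%%)\n",
    x$m_cut, x$r_cut, x$experiment_hits, x$expected_fp, 100 * x$fdr
  ))
  invisible(x)
}

#' @export
glance.mr_calibration <- function(x, ...) {
  tibble(
    m_cut = x$m_cut, r_cut = x$r_cut, fdr = x$fdr,
    expected_fp = x$expected_fp, mock_hits = x$mock_hits,
    experiment_hits = x$experiment_hits, mock_depth = x$mock_depth,
    experiment_depth = x$experiment_depth
  )
}

#' Detect translocations between control and treated map sets
#'
#' Full comparative pipeline: cognate control/treated maps are paired by
#' position (same-day replicates), restricted to proteins with complete
#' profiles in all maps, differenced into delta matrices, scored for
#' magnitude (M, per pair) and reproducibility (R, per pair combination),
#' combined, and thresholded. Hits are the proteins in the upper-right MR
#' quadrant.
#'
#' @param control,treated Lists of normalized profile tibbles of equal
#'   length (replicates in cognate order).
#' @param scheme A [fraction_scheme()].
#' @param mode Score combination mode, see [combine_mr()].
#' @param m_cut,r_cut Score cut-offs (defaults are the stringent empirical
#'   FDR-0 settings M = 2, R = 0.9; exploratory analyses commonly use
#'   M = 0.6, R = 0.7 at ~10% FDR).
#' @param mcd_fraction,df,seed Passed to [m_scores()].
#' @return An `mr_scores` tibble with an additional `significant` flag;
#'   attribute `"deltas"` holds the per-pair delta tibbles.
#' @export
detect_translocations <- function(control, treated, scheme = fraction_scheme(),
                                  mode = c("stringent", "sensitive"),
                                  m_cut = 2, r_cut = 0.9,
                                  mcd_fraction = 0.9, df = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (length(control) != length(treated)) {
    abort("Need equal numbers of cognate control and treated maps.")
  }
  common <- Reduce(intersect, c(
    lapply(control, function(m) m$protein_id),
    lapply(treated, function(m) m$protein_id)
  ))
  if (length(common) == 0) abort("No proteins shared across all maps.")
  restrict <- function(m) m[match(common, m$protein_id), , drop = FALSE]
  deltas <- purrr::map2(
    control, treated,
    function(c0, t0) compute_delta(restrict(c0), restrict(t0), scheme)
  )
  m_tbl <- bind_rows(lapply(seq_along(deltas), function(i) {
    ms <- m_scores(deltas[[i]], scheme,
      mcd_fraction = mcd_fraction, df = df,
      seed = seed + i
    )
    mutate(ms, pair = as.character(i))
  }))
  if (length(deltas) >= 2) {
    r_tbl <- r_scores(deltas, scheme)
    mr <- combine_mr(m_tbl, r_tbl, mode)
  } else {
    mr <- m_tbl |>
      group_by(.data$protein_id) |>
      summarise(m_combined = min(.data$m), .groups = "drop") |>
      mutate(r_combined = NA_real_)
    class(mr) <- c("mr_scores", class(mr))
  }
  mr$significant <- !is.na(mr$m_combined) & mr$m_combined >= m_cut &
    (length(deltas) < 2 | (!is.na(mr$r_combined) & mr$r_combined >= r_cut))
  attr(mr, "deltas") <- deltas
  attr(mr, "cutoffs") <- c(m_cut = m_cut, r_cut = r_cut)
  attr(mr, "mode") <- mode
  mr
}
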