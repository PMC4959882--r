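#' Combine classification results from replicate maps
#'
#' Per protein and compartment, negative decision scores are discarded and
#' the positive scores are summed across all maps in which the protein was
#' classified. Only clear positive classification decisions propagate, so a
#' compartment pair that is well separated in one map but poorly in another
#' contributes only through the better-resolved map; and a protein
#' predicted with a medium score in six replicate maps outranks a protein
#' with a single strong classification. The top cumulative score is the
#' combined prediction.
#'
#' @param results List of classification tibbles from [classify_map()] (or a
#'   single tibble) sharing one compartment list.
#' @return A cumulative classification tibble (`protein_id`, `n_maps`,
#'   floored-and-summed `score_*` columns, `top_prediction`, `top_score`);
#'   attribute `cumulative = TRUE`. If every cumulative score of a protein
#'   is 0 (no positive score in any map), the top prediction falls back to
#'   the best single-map guess.
#' @export
combine_maps <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  comp_sets <- lapply(results, attr, "compartments")
  compartments <- comp_sets[[1]]
  if (!all(vapply(comp_sets, identical, logical(1), compartments))) {
    abort("All classification results must share one compartment list.")
  }
  score_cols <- paste0("score_", compartments)
  all_rows <- bind_rows(lapply(results, function(r) {
    r[, c("protein_id", score_cols, "top_prediction", "top_score")]
  }))
  cum <- all_rows |>
    group_by(.data$protein_id) |>
    summarise(
      n_maps = n(),
      across(tidyselect::all_of(score_cols), function(v) sum(pmax(v, 0))),
      best_guess = .data$top_prediction[which.max(.data$top_score)],
      .groups = "drop"
    )
  dec <- as.matrix(cum[, score_cols])
  top <- max.col(dec, ties.method = "first")
  cum$top_prediction <- ifelse(
    rowSums(dec > 0) > 0, compartments[top], cum$best_guess
  )
  cum$top_score <- dec[cbind(seq_len(nrow(dec)), top)]
  cum$best_guess <- NULL
  attr(cum, "cumulative") <- TRUE
  attr(cum, "compartments") <- compartments
  cum
}

#' Percentile scores and confidence classes for cumulative predictions
#'
#' Raw cumulative SVM scores are not directly interpretable, so they are
#' converted to percent-ranks on a scale built from the correctly predicted
#' marker proteins: a protein's percentile is the percentage of correctly
#' predicted markers whose cumulative top score lies strictly below the
#' protein's. Percentiles map onto confidence classes via the bands
#' `< 1` Very low, `1-4` Low, `4-16` Medium, `16-52` High, `52-100`
#' Very High (bands derived from how map concordance grows with score).
#'
#' @param cumulative Cumulative classification tibble from [combine_maps()].
#' @param markers Marker tibble (`protein_id`, `compartment`).
#' @return The input with `percentile` and `confidence_class` columns
#'   (markers keep their own percentile; proteins absent from the marker
#'   scale are scored against it like any other).
#' @export
percentile_and_confidence <- function(cumulative, markers) {
  scale_tbl <- inner_join(cumulative, markers, by = "protein_id")
  correct <- scale_tbl[scale_tbl$top_prediction == scale_tbl$compartment, ]
  if (nrow(correct) == 0) {
    abort("No correctly predicted markers; cannot build a percentile scale.")
  }
  ref <- sort(correct$top_score)
  pct <- 100 * vapply(
    cumulative$top_score,
    function(s) mean(ref < s), numeric(1)
  )
  bands <- cut(pct,
    breaks = c(-Inf, 1, 4, 16, 52, Inf), right = FALSE,
    labels = c("Very low", "Low", "Medium", "High", "Very High")
  )
  cumulative$percentile <- pct
  cumulative$confidence_class <- as.character(bands)
  cumulative
}

#' Subcompartment prediction within a parent compartment
#'
#' Applies the same train/optimize/leave-one-out machinery to the proteins
#' already assigned to one parent compartment (e.g. ER membrane vs lumen,
#' or mitochondrial matrix vs inner vs outer membrane), using a
#' subcompartment marker set. Each replicate map is classified separately
#' and the results combined as in [combine_maps()].
#'
#' @param maps List of profile tibbles (replicate maps).
#' @param predictions Cumulative classification tibble; only proteins with
#'   `top_prediction == parent` are considered.
#' @param submarkers Tibble `protein_id`, `compartment` of subcompartment
#'   markers.
#' @param parent Name of the parent compartment.
#' @param scheme A [fraction_scheme()].
#' @param cfg An [svm_config()].
#' @param seed Fold seed.
#' @return List: `combined` (cumulative sub-class predictions), `loo`
#'   (per-map leave-one-out accuracy objects), `per_map` classification
#'   tibbles. Submarkers not predicted into the parent are dropped with a
#'   warning.
#' @export
predict_subcompartments <- function(maps, predictions, submarkers, parent,
                                    scheme = fraction_scheme(),
                                    cfg = svm_config(), seed = 1L) {
  parent_ids <- predictions$protein_id[predictions$top_prediction == parent]
  lost <- setdiff(submarkers$protein_id, parent_ids)
  if (length(lost) > 0) {
    warn(sprintf(
      "%d submarker(s) not predicted into '%s' were excluded.",
      length(lost), parent
    ))
  }
  submarkers <- submarkers[submarkers$protein_id %in% parent_ids, ]
  if (nrow(submarkers) == 0) abort("No submarkers among the parent's proteins.")
  per_map <- list()
  loo <- list()
  for (i in seq_along(maps)) {
    sub_map <- maps[[i]][maps[[i]]$protein_id %in% parent_ids, , drop = FALSE]
    model <- train_svm(sub_map, submarkers, scheme, cfg, seed = seed + i)
    per_map[[i]] <- classify_map(model, sub_map, map_id = as.character(i))
    loo[[i]] <- loo_marker_accuracy(sub_map, submarkers, model)
  }
  list(combined = combine_maps(per_map), loo = loo, per_map = per_map)
}
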