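#' Z-filter predictions using the organellar/nuclear balance
#'
#' Nuclear-pore-complex and actin-binding-cluster markers have
#' characteristically low organellar-to-nuclear intensity ratios (ONB);
#' proteins predicted into these classes whose ONB deviates strongly from
#' the marker distribution are likely misassigned. Per filtered class, the
#' median and robust standard deviation (1.483 x median absolute deviation)
#' of the markers' log2 ONB are computed; each non-marker prediction gets
#' `z = (marker median - log2 ONB) / robust SD` and predictions with
#' `z > cutoff` are re-assigned to their second-highest-scoring compartment
#' when one with a positive score exists (otherwise the top class is kept
#' and the protein is logged).
#'
#' ONB is computed as `(organellar share + pseudocount) /
#' (nuclear share + pseudocount)` from the global distribution profile.
#'
#' @param predictions Cumulative classification tibble with `score_*`
#'   columns.
#' @param onc Tibble `protein_id`, `share_o`, `share_n` (e.g. from
#'   [onc_profiles()]).
#' @param markers Marker tibble; markers of a filtered class define its ONB
#'   distribution and are themselves never re-assigned.
#' @param cutoffs Named numeric vector: z cut-off per class to filter
#'   (default nuclear pore complex 5, actin-binding proteins 4).
#' @param pseudocount Added to both shares before the ratio.
#' @return List: `predictions` (with revised `top_prediction` and logical
#'   `reassigned`), `log` (tibble of all z-scored proteins: class, z,
#'   old/new prediction, whether a fallback was used).
#' @export
z_filter_reassign <- function(predictions, onc, markers,
                              cutoffs = c(
                                "Nuclear pore complex" = 5,
                                "Actin binding proteins" = 4
                              ),
                              pseudocount = 1e-4) {
  compartments <- attr(predictions, "compartments") %||%
    sub("^score_", "", grep("^score_", names(predictions), value = TRUE))
  score_cols <- paste0("score_", compartments)
  onb <- setNames(
    log2((onc$share_o + pseudocount) / (onc$share_n + pseudocount)),
    onc$protein_id
  )
  predictions$reassigned <- FALSE
  logs <- list()
  for (cls in names(cutoffs)) {
    mk_ids <- markers$protein_id[markers$compartment == cls]
    mk_onb <- onb[intersect(mk_ids, names(onb))]
    mk_onb <- mk_onb[is.finite(mk_onb)]
    if (length(mk_onb) < 2) {
      warn(sprintf("Too few '%s' markers with ONB values; class skipped.", cls))
      next
    }
    med <- median(mk_onb)
    rsd <- mad(mk_onb, constant = 1.483)
    if (rsd == 0) {
      abort(sprintf("Degenerate marker set for '%s': robust SD is 0.", cls))
    }
    in_class <- which(predictions$top_prediction == cls &
      !(predictions$protein_id %in% mk_ids) &
      predictions$protein_id %in% names(onb))
    if (length(in_class) == 0) next
    z <- (med - onb[predictions$protein_id[in_class]]) / rsd
    reject <- z > cutoffs[[cls]]
    new_pred <- predictions$top_prediction[in_class]
    fallback <- rep(FALSE, length(in_class))
    if (any(reject)) {
      sc <- as.matrix(predictions[in_class, score_cols, drop = FALSE])
      sc[, match(paste0("score_", cls), score_cols)] <- -Inf
      second <- max.col(sc, ties.method = "first")
      second_ok <- sc[cbind(seq_len(nrow(sc)), second)] > 0
      new_pred[reject & second_ok] <- compartments[second[reject & second_ok]]
      fallback <- reject & !second_ok
    }
    logs[[cls]] <- tibble(
      protein_id = predictions$protein_id[in_class],
      class = cls, z = unname(z),
      old_prediction = predictions$top_prediction[in_class],
      new_prediction = new_pred,
      rejected = unname(reject), kept_by_fallback = unname(fallback)
    )
    predictions$top_prediction[in_class] <- new_pred
    predictions$reassigned[in_class] <-
      predictions$reassigned[in_class] | (new_pred != cls)
  }
  list(
    predictions = predictions,
    log = if (length(logs) > 0) bind_rows(logs) else tibble()
  )
}
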