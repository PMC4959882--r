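#' MR plot of translocation scores
#'
#' Scatter of combined M (magnitude, -log10 Q of the robust outlier test)
#' against combined R (delta-profile reproducibility). Genuine movers
#' occupy the upper-right quadrant delimited by the cut-offs.
#'
#' @param mr An `mr_scores` tibble (e.g. from [detect_translocations()]).
#' @param m_cut,r_cut Quadrant boundaries; default to the cut-offs stored
#'   on the object, else M = 2, R = 0.9.
#' @return A ggplot object.
#' @export
plot_mr <- function(mr, m_cut = NULL, r_cut = NULL) {
  cuts <- attr(mr, "cutoffs")
  m_cut <- m_cut %||% unname(cuts["m_cut"]) %||% 2
  r_cut <- r_cut %||% unname(cuts["r_cut"]) %||% 0.9
  df <- as_tibble(mr)
  df$hit <- !is.na(df$m_combined) & !is.na(df$r_combined) &
    df$m_combined >= m_cut & df$r_combined >= r_cut
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r_combined, y = .data$m_combined,
    colour = .data$hit
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = r_cut, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = m_cut, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red3"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "R (reproducibility of translocation)",
      y = "M (magnitude of translocation)"
    ) +
    ggplot2::theme_classic()
}

#' @rdname plot_mr
#' @param object An `mr_scores` tibble.
#' @param ... Passed to [plot_mr()].
#' @export
autoplot.mr_scores <- function(object, ...) plot_mr(object, ...)

#' PCA map of organellar clusters
#'
#' @param object A `map_pca` from [pca_project()].
#' @param labels Optional tibble `protein_id`, `compartment` to colour by
#'   (e.g. markers or predictions).
#' @param dims Two components to plot (default PC1 vs PC3, which usually
#'   separates organellar clusters best).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.map_pca <- function(object, labels = NULL, dims = c(1, 3), ...) {
  dims <- dims[dims <= (ncol(object$scores) - 1)]
  if (length(dims) < 2) dims <- c(1, 2)
  cols <- paste0("PC", dims)
  df <- object$scores
  if (!is.null(labels)) {
    df <- left_join(df, labels, by = "protein_id")
  } else {
    df$compartment <- NA_character_
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[cols[1]]], y = .data[[cols[2]]],
    colour = .data$compartment
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(
      x = sprintf(
        "%s (%.1f%%)", cols[1],
        100 * object$explained_variance[dims[1]]
      ),
      y = sprintf(
        "%s (%.1f%%)", cols[2],
        100 * object$explained_variance[dims[2]]
      )
    ) +
    ggplot2::theme_classic()
}

#' Volcano plot of global pool changes
#'
#' @param object A `global_change` tibble from [lfq_compare()].
#' @param ... Ignored.
#' @return A ggplot object, faceted by global fraction.
#' @export
autoplot.global_change <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$log2_diff, y = .data$neg_log10_p, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~fraction) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red3"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "log2 fold change (treated - control)",
      y = "-log10 p"
    ) +
    ggplot2::theme_classic()
}

#' Fractionation profiles of selected proteins
#'
#' Line plot of normalized profiles (proportion pelleted per fraction) for
#' a handful of proteins, e.g. a translocation hit and its old and new
#' neighbours.
#'
#' @param map A normalized profile tibble.
#' @param proteins Character vector of protein ids to show.
#' @param scheme A [fraction_scheme()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(map, proteins, scheme = fraction_scheme()) {
  df <- map[map$protein_id %in% proteins, c("protein_id", profile_cols(scheme))]
  long <- tidyr::pivot_longer(df, -"protein_id",
    names_to = "fraction", values_to = "proportion"
  )
  long$fraction <- factor(
    sub("^ratio_", "", long$fraction),
    levels = scheme$profile_fractions
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$fraction, y = .data$proportion,
    group = .data$protein_id, colour = .data$protein_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction", y = "proportion pelleted") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
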