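#' Stringency-filter the SILAC ratio data (Group 1)
#'
#' Applies the profile-data stringency filter to a parsed proteinGroups
#' table: reverse hits, contaminants and proteins only identified by site
#' are removed; a protein is retained only if it has a complete profile of
#' five finite positive SILAC ratios, and in every fraction either three or
#' more quantification events, or exactly two events with a ratio
#' variability below 30% in that fraction.
#'
#' The two-event rescue is applied per fraction: every fraction with fewer
#' than three events must individually have two events and pass the
#' variability test. `max_rescued` optionally caps how many fractions of one
#' protein may be rescued this way (default `Inf`, i.e. all five).
#'
#' @param records Tibble from [read_protein_groups()].
#' @param scheme A [fraction_scheme()].
#' @param min_count Minimum quantification events per fraction (default 3).
#' @param rescue_variability Maximum percent ratio variability for the
#'   two-event rescue (default 30).
#' @param max_rescued Maximum number of rescued (2-event) fractions per
#'   protein.
#' @return A profile tibble: `protein_id`, `gene_name` and the five raw H/L
#'   `ratio_*` columns, carrying attribute `kind = "raw_HL"`.
#' @export
filter_profile_group <- function(records, scheme = fraction_scheme(),
                                 min_count = 3, rescue_variability = 30,
                                 max_rescued = Inf) {
  rcols <- profile_cols(scheme)
  ccols <- paste0("ratio_count_", scheme$profile_fractions)
  vcols <- paste0("ratio_variability_", scheme$profile_fractions)
  missing <- setdiff(rcols, names(records))
  if (length(missing) > 0) {
    abort(paste0("Ratio column(s) absent: ", paste(missing, collapse = ", ")))
  }

  keep_flags <- !(records$is_reverse | records$is_contaminant |
    records$is_only_by_site)
  ratios <- as.matrix(records[, rcols])
  complete <- rowSums(is.finite(ratios) & ratios > 0) == length(rcols)

  have_counts <- all(ccols %in% names(records))
  if (have_counts) {
    counts <- as.matrix(records[, ccols])
    counts[is.na(counts)] <- 0
    ok_count <- counts >= min_count
    if (all(vcols %in% names(records))) {
      variab <- as.matrix(records[, vcols])
      rescued <- !ok_count & counts == (min_count - 1) &
        is.finite(variab) & variab < rescue_variability
    } else {
      rescued <- matrix(FALSE, nrow(records), length(rcols))
    }
    count_pass <- rowSums(ok_count | rescued) == length(rcols) &
      rowSums(rescued) <= max_rescued
  } else {
    count_pass <- rep(TRUE, nrow(records))
  }

  keep <- keep_flags & complete & count_pass
  out <- records[keep, c("protein_id", "gene_name", rcols)]
  if (nrow(out) == 0) {
    warn("No proteins passed the profile stringency filter; returning an empty table.")
  }
  out <- as_tibble(out)
  attr(out, "kind") <- "raw_HL"
  out
}

#' Filter the N/O/C intensity data (Group 2)
#'
#' Keeps proteins identified with at least `min_msms` MS/MS events in at
#' least one of the global (nuclear/organellar/cytosolic) fractions, after
#' removing reverse/contaminant/site-only entries. Raw intensities are
#' returned unchanged.
#'
#' @inheritParams filter_profile_group
#' @param min_msms Minimum MS/MS events required in at least one global
#'   fraction (default 2).
#' @return Tibble with `protein_id`, `gene_name`, `mol_weight_kda` and the
#'   three global `intensity_*` columns.
#' @export
filter_intensity_group <- function(records, scheme = fraction_scheme(),
                                   min_msms = 2) {
  icols <- paste0("intensity_", scheme$global_fractions)
  mcols <- paste0("msms_", scheme$global_fractions)
  missing <- setdiff(icols, names(records))
  if (length(missing) > 0) {
    abort(paste0("Intensity column(s) absent: ", paste(missing, collapse = ", ")))
  }
  keep <- !(records$is_reverse | records$is_contaminant | records$is_only_by_site)
  if (all(mcols %in% names(records))) {
    msms <- as.matrix(records[, mcols])
    msms[is.na(msms)] <- 0
    keep <- keep & rowSums(msms >= min_msms) >= 1
  }
  cols <- intersect(
    c("protein_id", "gene_name", "mol_weight_kda", icols),
    names(records)
  )
  as_tibble(records[keep, cols])
}

#' Filter the LFQ data (Group 3)
#'
#' Keeps proteins with at least one MS/MS event in at least one global
#' fraction. Missing LFQ values are preserved as `NA`.
#'
#' @inheritParams filter_profile_group
#' @return Tibble with `protein_id`, `gene_name` and the `lfq_*` columns.
#' @export
filter_lfq_group <- function(records, scheme = fraction_scheme()) {
  lcols <- grep("^lfq_", names(records), value = TRUE)
  if (length(lcols) == 0) abort("No LFQ columns present.")
  mcols <- paste0("msms_", scheme$global_fractions)
  keep <- !(records$is_reverse | records$is_contaminant | records$is_only_by_site)
  if (any(mcols %in% names(records))) {
    msms <- as.matrix(records[, intersect(mcols, names(records))])
    msms[is.na(msms)] <- 0
    keep <- keep & rowSums(msms >= 1) >= 1
  }
  as_tibble(records[keep, c("protein_id", "gene_name", lcols)])
}

#' Summarise how many proteins each filter rule removed
#'
#' @param records Parsed proteinGroups tibble.
#' @param scheme A [fraction_scheme()].
#' @return A tibble with one row per filter rule and the number of proteins
#'   dropped by it (applied sequentially for Group 1).
#' @export
filter_report <- function(records, scheme = fraction_scheme()) {
  n0 <- nrow(records)
  flagged <- records$is_reverse | records$is_contaminant | records$is_only_by_site
  r1 <- records[!flagged, ]
  g1 <- filter_profile_group(records, scheme)
  g2 <- filter_intensity_group(records, scheme)
  g3 <- tryCatch(filter_lfq_group(records, scheme), error = function(e) NULL)
  tibble(
    rule = c(
      "input", "reverse/contaminant/site-only",
      "profile completeness + counts (Group 1 kept)",
      "intensity MS/MS (Group 2 kept)", "LFQ MS/MS (Group 3 kept)"
    ),
    n = c(
      n0, n0 - nrow(r1), nrow(g1), nrow(g2),
      if (is.null(g3)) NA_integer_ else nrow(g3)
    )
  )
}
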