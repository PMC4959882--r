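#' Column-name dialect of a proteinGroups table
#'
#' MaxQuant header names drift between versions; the dialect maps the
#' standardized column roles used by [read_protein_groups()] onto concrete
#' header names. `{fraction}` in a template is replaced by each fraction
#' label of the scheme. Defaults follow MaxQuant 1.5 naming.
#'
#' @param protein_id,gene_name,mol_weight,reverse,contaminant,only_by_site
#'   Header names of the scalar columns.
#' @param ratio,ratio_count,ratio_variability Templates for the per-profile-
#'   fraction SILAC ratio columns.
#' @param intensity,lfq,msms Templates for per-fraction intensity, LFQ and
#'   MS/MS count columns (used for both profile and global fractions, as
#'   present).
#' @return A named list of class `pg_dialect`.
#' @export
pg_dialect <- function(protein_id = "Protein IDs",
                       gene_name = "Gene names",
                       mol_weight = "Mol. weight [kDa]",
                       reverse = "Reverse",
                       contaminant = "Potential contaminant",
                       only_by_site = "Only identified by site",
                       ratio = "Ratio H/L normalized {fraction}",
                       ratio_count = "Ratio H/L count {fraction}",
                       ratio_variability = "Ratio H/L variability [%] {fraction}",
                       intensity = "Intensity {fraction}",
                       lfq = "LFQ intensity {fraction}",
                       msms = "MS/MS count {fraction}") {
  structure(
    list(
      protein_id = protein_id, gene_name = gene_name, mol_weight = mol_weight,
      reverse = reverse, contaminant = contaminant, only_by_site = only_by_site,
      ratio = ratio, ratio_count = ratio_count,
      ratio_variability = ratio_variability,
      intensity = intensity, lfq = lfq, msms = msms
    ),
    class = "pg_dialect"
  )
}

.expand_template <- function(template, fraction) {
  stringr::str_replace(template, stringr::fixed("{fraction}"), fraction)
}

#' Read a MaxQuant proteinGroups-dialect table
#'
#' Parses a tab-separated protein-level quantification table into one tidy
#' row per protein group with standardized column names: `protein_id`,
#' `gene_name`, `mol_weight_kda`, the `is_reverse` / `is_contaminant` /
#' `is_only_by_site` flags, and per-fraction columns `ratio_*`,
#' `ratio_count_*`, `ratio_variability_*`, `intensity_*`, `lfq_*`, `msms_*`
#' for every fraction whose source column is present in the file.
#'
#' Missing or zero SILAC ratios and LFQ intensities are represented as `NA`
#' (MaxQuant writes 0 or "NaN" for non-quantified cells); raw intensities of
#' 0 are kept as 0, since a zero intensity is a valid measurement of
#' absence.
#'
#' @param path Path to the tab-separated file.
#' @param scheme A [fraction_scheme()].
#' @param dialect A [pg_dialect()] describing the header names.
#' @return A tibble with one row per protein group.
#' @export
read_protein_groups <- function(path, scheme = fraction_scheme(),
                                dialect = pg_dialect()) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c(dialect$protein_id)
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0) {
    abort(paste0(
      "proteinGroups table is missing required column(s): ",
      paste(absent, collapse = ", ")
    ))
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  flag <- function(col) {
    if (col %in% names(raw)) {
      v <- raw[[col]]
      !is.na(v) & v != "" & v != "0"
    } else {
      rep(FALSE, nrow(raw))
    }
  }

  out <- tibble(
    protein_id = raw[[dialect$protein_id]],
    gene_name = if (dialect$gene_name %in% names(raw)) {
      raw[[dialect$gene_name]]
    } else {
      NA_character_
    },
    mol_weight_kda = if (dialect$mol_weight %in% names(raw)) {
      num(raw[[dialect$mol_weight]])
    } else {
      NA_real_
    },
    is_reverse = flag(dialect$reverse),
    is_contaminant = flag(dialect$contaminant),
    is_only_by_site = flag(dialect$only_by_site)
  )

  dup <- out$protein_id[duplicated(out$protein_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate protein_id(s) in table: ",
      paste(unique(dup), collapse = ", ")
    ))
  }

  add_numeric <- function(out, template, fractions, prefix, zero_is_na) {
    for (f in fractions) {
      src <- .expand_template(template, f)
      if (src %in% names(raw)) {
        v <- num(raw[[src]])
        if (zero_is_na) v[!is.na(v) & v == 0] <- NA_real_
        out[[paste0(prefix, f)]] <- v
      }
    }
    out
  }

  pf <- scheme$profile_fractions
  gf <- scheme$global_fractions
  out <- add_numeric(out, dialect$ratio, pf, "ratio_", zero_is_na = TRUE)
  out <- add_numeric(out, dialect$ratio_count, pf, "ratio_count_", zero_is_na = FALSE)
  out <- add_numeric(out, dialect$ratio_variability, pf, "ratio_variability_", zero_is_na = FALSE)
  out <- add_numeric(out, dialect$intensity, c(pf, gf), "intensity_", zero_is_na = FALSE)
  out <- add_numeric(out, dialect$lfq, c(pf, gf), "lfq_", zero_is_na = TRUE)
  out <- add_numeric(out, dialect$msms, c(pf, gf), "msms_", zero_is_na = FALSE)
  out
}
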