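#' Proteomic-ruler protein copy numbers and concentrations
#'
#' The total histone MS signal is proportional to cellular DNA content, so
#' anchoring it to the DNA mass expected from the genome size and ploidy
#' converts relative intensities into absolute copies per cell:
#' total protein mass per cell = DNA mass x (sum of all intensities / sum
#' of histone intensities), and
#' `copies_i = (intensity_i / sum intensities) x total protein mass x
#' N_Avogadro / MW_i`. Cell volume follows from an assumed total protein
#' concentration, giving molar cellular concentrations.
#'
#' MS intensities are proportional to protein mass, which is what the
#' histone/DNA anchor requires, so by default intensities enter the formula
#' unchanged. `normalize_mw = TRUE` instead divides intensities by the
#' protein's molecular weight and rescales by the average molecular weight
#' before computing shares (a molar-like scale some workflows use).
#'
#' @param tbl Tibble with `protein_id`, `mol_weight_kda` and one or more
#'   whole-cell intensity columns (replicates).
#' @param intensity_cols Tidy-selection of the intensity columns (default:
#'   every column starting with `"intensity"`).
#' @param histone_ids Character vector of histone `protein_id`s.
#' @param ploidy Chromosomal ploidy of the cell (default 3, a reasonable
#'   estimate for HeLa).
#' @param total_protein_conc Assumed cellular protein concentration in g/L
#'   (default 200).
#' @param haploid_genome_pg Mass of one haploid genome in picograms
#'   (default 3.1 for human).
#' @param normalize_mw Normalize intensities to average molecular mass
#'   before computing shares (default `FALSE`).
#' @return A `copy_table` tibble: `protein_id`, `mol_weight_kda`,
#'   per-replicate `copies_*` columns, `copies` (median across replicates),
#'   `conc_nM` (cellular concentration from the median copies). Attribute
#'   `cell_volume_L` holds the per-replicate volume estimates.
#' @export
proteomic_ruler <- function(tbl,
                            intensity_cols = tidyselect::starts_with("intensity"),
                            histone_ids, ploidy = 3, total_protein_conc = 200,
                            haploid_genome_pg = 3.1, normalize_mw = FALSE) {
  icols <- names(tidyselect::eval_select(rlang::enquo(intensity_cols), tbl))
  if (length(icols) == 0) abort("No intensity columns selected.")
  hist_rows <- tbl$protein_id %in% histone_ids
  if (!any(hist_rows)) abort("No histones among the quantified proteins.")
  mw_da <- tbl$mol_weight_kda * 1000
  if (any(!is.finite(mw_da) | mw_da <= 0)) {
    abort("All proteins need a positive molecular weight.")
  }
  dna_mass_g <- haploid_genome_pg * 1e-12 * ploidy
  copies_rep <- matrix(NA_real_, nrow(tbl), length(icols))
  volumes <- numeric(length(icols))
  for (j in seq_along(icols)) {
    intens <- tbl[[icols[j]]]
    intens[is.na(intens)] <- 0
    i_norm <- if (normalize_mw) intens / mw_da * mean(mw_da) else intens
    total_mass_g <- dna_mass_g * sum(i_norm) / sum(i_norm[hist_rows])
    copies_rep[, j] <- (i_norm / sum(i_norm)) * total_mass_g * .AVOGADRO / mw_da
    volumes[j] <- total_mass_g / total_protein_conc
  }
  colnames(copies_rep) <- paste0("copies_", seq_along(icols))
  med_copies <- apply(copies_rep, 1, median)
  med_volume <- median(volumes)
  out <- bind_cols(
    tibble(protein_id = tbl$protein_id, mol_weight_kda = tbl$mol_weight_kda),
    as_tibble(as.data.frame(copies_rep)),
    tibble(
      copies = med_copies,
      conc_nM = 1e9 * med_copies / (.AVOGADRO * med_volume)
    )
  )
  attr(out, "cell_volume_L") <- volumes
  class(out) <- c("copy_table", class(out))
  out
}

#' Paired test for copy-number changes between conditions
#'
#' Log-transformed replicate copy numbers are compared with a two-tailed
#' paired t-test (replicates paired by position). No multiple-testing
#' correction is applied: movement between compartments is assessed in
#' separate, FDR-controlled tests, so false positives here are not
#' detrimental. For significant proteins (`p < alpha`, strict) the control
#' and treated medians are reported separately; otherwise the overall
#' median across all replicates is used. All-zero differences give an
#' undefined t statistic, reported as not significant.
#'
#' @param control,treated Matrices or data frames of replicate copy numbers
#'   (rows = proteins, equal column counts >= 2), plus a `protein_id`
#'   vector.
#' @param protein_id Protein identifiers.
#' @param alpha Significance level (default 0.01).
#' @return Tibble: `protein_id`, `p_value`, `significant`,
#'   `median_control`, `median_treated`, `median_used` (pooled when not
#'   significant, otherwise `NA` with the split medians authoritative).
#' @export
copy_change_test <- function(protein_id, control, treated, alpha = 0.01) {
  control <- as.matrix(control)
  treated <- as.matrix(treated)
  if (ncol(control) != ncol(treated) || ncol(control) < 2) {
    abort("Need equal replicate counts of at least 2 per condition.")
  }
  p <- vapply(seq_len(nrow(control)), function(i) {
    lc <- log10(control[i, ])
    lt <- log10(treated[i, ])
    tryCatch(
      t.test(lt, lc, paired = TRUE)$p.value,
      error = function(e) NA_real_ # zero differences: t undefined
    )
  }, numeric(1))
  sig <- !is.na(p) & p < alpha
  med_c <- apply(control, 1, median)
  med_t <- apply(treated, 1, median)
  med_all <- apply(cbind(control, treated), 1, median)
  tibble(
    protein_id = protein_id, p_value = unname(p), significant = sig,
    median_control = ifelse(sig, med_c, NA_real_),
    median_treated = ifelse(sig, med_t, NA_real_),
    median_used = ifelse(sig, NA_real_, med_all)
  )
}

#' Copy flux between global fractions
#'
#' Multiplies a protein's copy number by the change in its share of each
#' global fraction to obtain the number of copies entering (positive) or
#' leaving (negative) that fraction. With unchanged total copies the three
#' fluxes sum to zero.
#'
#' @param copies Named numeric vector (or tibble with `protein_id`,
#'   `copies`).
#' @param onc_before,onc_after ONC profile tibbles.
#' @return Tibble `protein_id`, `flux_o`, `flux_n`, `flux_c`.
#' @export
compartment_flux <- function(copies, onc_before, onc_after) {
  if (is.data.frame(copies)) {
    copies <- setNames(copies$copies, copies$protein_id)
  }
  common <- Reduce(intersect, list(
    names(copies), onc_before$protein_id, onc_after$protein_id
  ))
  b <- onc_before[match(common, onc_before$protein_id), ]
  a <- onc_after[match(common, onc_after$protein_id), ]
  k <- copies[common]
  tibble(
    protein_id = common,
    flux_o = unname(k * (a$share_o - b$share_o)),
    flux_n = unname(k * (a$share_n - b$share_n)),
    flux_c = unname(k * (a$share_c - b$share_c))
  )
}

#' Organelle protein-mass model with nuclear-contamination redistribution
#'
#' Each protein's cellular mass (copies x molecular weight) is split across
#' the cytosolic, nuclear and organellar pools by its global distribution
#' shares. Because the crude nuclear fraction carries unreleased organellar
#' material, mass is then redistributed by global class: for mostly nuclear
#' (`N`) and nuclear/cytosolic (`N/C`) proteins the organellar pool is
#' added to the nuclear pool; for mostly organellar (`O`) and
#' organellar/cytosolic (`O/C`) proteins the nuclear pool is added to the
#' organellar pool; mostly cytosolic (`C`) and broad (`B`) profiles are
#' left unchanged. The organellar pool is finally apportioned to
#' compartments by the protein's top SVM prediction, with two special
#' cases: large-protein-complex mass goes to the cytosol, and
#' actin-binding-cluster mass goes to the cytoskeleton (organellar +
#' nuclear pools) and soluble pool (cytosolic). Total mass is conserved
#' exactly.
#'
#' @param tbl Tibble with `protein_id`, `copies`, `mol_weight_kda`,
#'   `share_o`, `share_n`, `share_c`, `global_class`, `top_prediction`.
#'   Proteins with a missing class or prediction fall back to class `B` /
#'   compartment `"Unassigned"` and are flagged.
#' @param lpc_class,abp_class Names of the large-protein-complex and
#'   actin-binding compartments in `top_prediction`.
#' @return List of class `mass_model`: `per_protein` (post-redistribution
#'   masses in kDa-copies units and destination compartment),
#'   `by_compartment` (total mass and percent of cellular protein mass),
#'   `total_mass`.
#' @export
mass_model <- function(tbl, lpc_class = "Large protein complexes",
                       abp_class = "Actin binding proteins") {
  tbl <- mutate(tbl,
    fallback = is.na(.data$global_class) | is.na(.data$top_prediction),
    global_class = ifelse(is.na(.data$global_class), "B", .data$global_class),
    top_prediction = ifelse(is.na(.data$top_prediction), "Unassigned",
      .data$top_prediction
    )
  )
  mass <- tbl$copies * tbl$mol_weight_kda
  mc <- mass * tbl$share_c
  mn <- mass * tbl$share_n
  mo <- mass * tbl$share_o
  cls <- tbl$global_class
  to_nuclear <- cls %in% c("N", "N/C")
  to_organellar <- cls %in% c("O", "O/C")
  mn2 <- ifelse(to_nuclear, mn + mo, ifelse(to_organellar, 0, mn))
  mo2 <- ifelse(to_organellar, mo + mn, ifelse(to_nuclear, 0, mo))
  per <- tibble(
    protein_id = tbl$protein_id, mass = mass,
    mass_c = mc, mass_n = mn2, mass_o = mo2,
    top_prediction = tbl$top_prediction, fallback = tbl$fallback
  )
  pools <- list()
  add_pool <- function(pools, name, amount) {
    pools[[name]] <- (pools[[name]] %||% 0) + sum(amount)
    pools
  }
  is_lpc <- per$top_prediction == lpc_class
  is_abp <- per$top_prediction == abp_class
  std <- !is_lpc & !is_abp
  pools <- add_pool(pools, "Nucleus", per$mass_n[!is_abp])
  pools <- add_pool(pools, "Cytosol", per$mass_c[std])
  for (comp in unique(per$top_prediction[std])) {
    rows <- std & per$top_prediction == comp
    pools <- add_pool(pools, comp, per$mass_o[rows])
  }
  # large complexes pellet without membranes: count their mass as cytosolic
  pools <- add_pool(pools, "Cytosol", per$mass_o[is_lpc] + per$mass_c[is_lpc])
  # actin cluster: pelleted pools are cytoskeletal, the rest soluble
  pools <- add_pool(pools, "Cytoskeleton", per$mass_o[is_abp] + per$mass_n[is_abp])
  pools <- add_pool(pools, "Cytosol", per$mass_c[is_abp])
  by_comp <- tibble(
    compartment = names(pools),
    mass = unname(unlist(pools))
  )
  total <- sum(mass)
  by_comp$pct_of_cell <- 100 * by_comp$mass / total
  by_comp <- arrange(by_comp, dplyr::desc(.data$mass))
  structure(
    list(per_protein = per, by_compartment = by_comp, total_mass = total),
    class = "mass_model"
  )
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model> total protein mass:", format(x$total_mass, digits = 4), "\n")
  print(x$by_compartment)
  invisible(x)
}
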