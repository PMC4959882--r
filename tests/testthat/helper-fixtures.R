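# Shared fixtures, all generated in code.

# A small, well-separated 5-compartment layout for classifier tests.
small_compartments <- function(n_proteins = 30, n_markers = 12) {
  tibble::tribble(
    ~compartment, ~organellar_release, ~nuclear_baseline, ~cytosolic_pool,
    ~c1, ~c2, ~c3, ~c4, ~c5,
    "Mitochondria", 0.60, 0.02, 0.02, 0.55, 0.25, 0.10, 0.06, 0.04,
    "Lysosomes", 0.90, 0.01, 0.02, 0.15, 0.50, 0.20, 0.10, 0.05,
    "Golgi", 0.65, 0.02, 0.02, 0.08, 0.15, 0.45, 0.22, 0.10,
    "ER", 0.70, 0.03, 0.02, 0.10, 0.20, 0.25, 0.30, 0.15,
    "Endosomes", 0.80, 0.02, 0.05, 0.04, 0.08, 0.15, 0.38, 0.35
  ) |>
    dplyr::mutate(n_proteins = n_proteins, n_markers = n_markers, .after = 1)
}

small_sim_spec <- function(seed = 11L, n_proteins = 30, n_markers = 12, ...) {
  sim_spec(
    compartments = small_compartments(n_proteins, n_markers),
    seed = seed, ...
  )
}

# Write a minimal proteinGroups-dialect TSV and return its path.
write_toy_pg <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                           .local_envir = parent.frame())) {
  readr::write_tsv(rows, path, progress = FALSE, na = "NaN")
  path
}

# One toy proteinGroups row set with full columns for the default scheme.
toy_pg_rows <- function() {
  sc <- fraction_scheme()
  tbl <- tibble::tibble(
    `Protein IDs` = c("P1", "P2", "REV__P3"),
    `Gene names` = c("GNA1", "GNA2", "GNA3"),
    `Mol. weight [kDa]` = c(50, 75, 20),
    Reverse = c("", "", "+"),
    `Potential contaminant` = c("", "", ""),
    `Only identified by site` = c("", "", "")
  )
  for (f in sc$profile_fractions) {
    tbl[[paste0("Ratio H/L normalized ", f)]] <- c(1.2, 0.8, 1.0)
    tbl[[paste0("Ratio H/L count ", f)]] <- c(4, 3, 3)
    tbl[[paste0("Ratio H/L variability [%] ", f)]] <- c(10, 12, 15)
    tbl[[paste0("MS/MS count ", f)]] <- c(6, 5, 4)
  }
  for (g in sc$global_fractions) {
    tbl[[paste0("Intensity ", g)]] <- c(1e6, 2e6, 0)
    tbl[[paste0("LFQ intensity ", g)]] <- c(1.5e6, 2.5e6, 0)
    tbl[[paste0("MS/MS count ", g)]] <- c(3, 2, 1)
  }
  tbl
}

# Random points on the 4-simplex (5 parts).
random_simplex <- function(n, k = 5) {
  g <- matrix(stats::rexp(n * k), n, k)
  g / rowSums(g)
}

# Build a classification tibble by hand (for combine/percentile tests).
manual_classification <- function(protein_id, scores, map_id = "1") {
  compartments <- colnames(scores)
  out <- tibble::tibble(protein_id = protein_id, map_id = map_id)
  for (comp in compartments) out[[paste0("score_", comp)]] <- scores[, comp]
  top <- max.col(scores, ties.method = "first")
  out$top_prediction <- compartments[top]
  out$top_score <- scores[cbind(seq_len(nrow(scores)), top)]
  attr(out, "cumulative") <- FALSE
  attr(out, "compartments") <- compartments
  out
}
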