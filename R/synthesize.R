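#' Default synthetic compartment layout
#'
#' Eight compartments with distinct 5-fraction centroid profiles on the
#' simplex, marker counts, and organellar release efficiencies spanning the
#' experimentally observed range (lysosomes released almost completely,
#' plasma membrane only around 45% because membrane sheets of partially
#' lysed cells pellet with the nuclei).
#'
#' @return Tibble: `compartment`, `n_proteins`, `n_markers`,
#'   `organellar_release`, `nuclear_baseline`, `cytosolic_pool`, and the
#'   centroid columns `c1`..`c5`.
#' @export
sim_compartments <- function() {
  tibble::tribble(
    ~compartment, ~n_proteins, ~n_markers, ~organellar_release,
    ~nuclear_baseline, ~cytosolic_pool, ~c1, ~c2, ~c3, ~c4, ~c5,
    "Mitochondria", 60, 15, 0.60, 0.02, 0.02, 0.55, 0.25, 0.10, 0.06, 0.04,
    "Lysosomes", 40, 12, 0.90, 0.01, 0.02, 0.15, 0.50, 0.20, 0.10, 0.05,
    "Peroxisomes", 25, 8, 0.70, 0.02, 0.02, 0.10, 0.30, 0.40, 0.12, 0.08,
    "Golgi", 35, 10, 0.65, 0.02, 0.02, 0.08, 0.15, 0.45, 0.22, 0.10,
    "Plasma membrane", 60, 15, 0.45, 0.05, 0.02, 0.32, 0.12, 0.14, 0.24, 0.18,
    "ER", 60, 15, 0.70, 0.03, 0.02, 0.10, 0.20, 0.25, 0.30, 0.15,
    "Endosomes", 40, 12, 0.80, 0.02, 0.05, 0.05, 0.10, 0.20, 0.40, 0.25,
    "Large protein complexes", 50, 12, 0.30, 0.05, 0.60, 0.04, 0.06, 0.10, 0.25, 0.55
  )
}

#' Specification of a synthetic organellar-map experiment
#'
#' Bundles every parameter of the seeded generator: compartment layout with
#' centroids, logistic-normal profile noise, day-batch effects, replicate
#' structure, injected translocations, the histone block for the proteomic
#' ruler, and LFQ noise/dropout. With a fixed seed all generator outputs
#' are bit-identical.
#'
#' @param compartments Compartment tibble, see [sim_compartments()].
#' @param noise_sd Logistic-normal noise SD on log-centroids (default 0.12).
#' @param batch_sd SD of the shared per-day, per-fraction log shift
#'   (default 0.03, sized so inter-day map correlation is about 0.95).
#' @param n_control,n_treated Replicate counts; replicate r of both
#'   conditions shares day r (cognate pairs).
#' @param translocations Tibble `from`, `to`, `n`, `lambda`: `n` non-marker
#'   proteins of compartment `from` get a treated centroid
#'   `(1 - lambda) * from + lambda * to`.
#' @param n_histones Number of histone proteins; their summed mass is tied
#'   to the DNA mass implied by `ploidy`, as the proteomic ruler assumes.
#' @param ploidy,haploid_genome_pg Passed through to the ground truth.
#' @param lfq_noise_sd Log-normal SD of LFQ replicate noise.
#' @param dropout_rate Missing-value rate for low-intensity LFQ values.
#' @param scheme A [fraction_scheme()].
#' @param seed Integer master seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(compartments = sim_compartments(), noise_sd = 0.12,
                     batch_sd = 0.03, n_control = 3, n_treated = 3,
                     translocations = NULL, n_histones = 10, ploidy = 3,
                     haploid_genome_pg = 3.1, lfq_noise_sd = 0.1,
                     dropout_rate = 0.05, scheme = fraction_scheme(),
                     seed = 17L) {
  cent <- as.matrix(compartments[, paste0("c", 1:5)])
  if (any(abs(rowSums(cent) - 1) > 1e-9) || any(cent < 0)) {
    abort("Compartment centroids must lie on the simplex.")
  }
  if (noise_sd == 0 && any(cent == 0)) {
    abort("Zero centroid entries are degenerate when noise is off.")
  }
  if (!is.null(translocations)) {
    bad_from <- setdiff(translocations$from, compartments$compartment)
    bad_to <- setdiff(translocations$to, compartments$compartment)
    if (length(c(bad_from, bad_to)) > 0) {
      abort("Translocation from/to compartments must exist.")
    }
    if (any(translocations$lambda < 0 | translocations$lambda > 1)) {
      abort("Mixing fraction lambda must be in [0, 1].")
    }
  }
  structure(
    list(
      compartments = compartments, noise_sd = noise_sd, batch_sd = batch_sd,
      n_control = n_control, n_treated = n_treated,
      translocations = translocations, n_histones = n_histones,
      ploidy = ploidy, haploid_genome_pg = haploid_genome_pg,
      lfq_noise_sd = lfq_noise_sd, dropout_rate = dropout_rate,
      scheme = scheme, seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

# deterministic protein roster: ids, compartments, marker flags, centroids
.sim_roster <- function(spec) {
  comp <- spec$compartments
  cent <- as.matrix(comp[, paste0("c", 1:5)])
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    n <- comp$n_proteins[i]
    tag <- toupper(substr(gsub("[^A-Za-z]", "", comp$compartment[i]), 1, 4))
    tibble(
      protein_id = sprintf("%s_%03d", tag, seq_len(n)),
      compartment = comp$compartment[i],
      is_marker = seq_len(n) <= comp$n_markers[i]
    )
  })
  roster <- bind_rows(rows)
  roster$centroid <- cent[match(roster$compartment, comp$compartment), ,
    drop = FALSE
  ]
  roster
}

.softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# one raw-H/L map from per-protein centroids plus noise and a day shift
.sim_one_map <- function(centroids, spec, day_shift, noise_seed, map_id,
                         condition, replicate) {
  n <- nrow(centroids)
  logc <- log(centroids)
  noise <- if (spec$noise_sd > 0) {
    withr::with_seed(noise_seed, matrix(rnorm(n * 5, 0, spec$noise_sd), n, 5))
  } else {
    matrix(0, n, 5)
  }
  p <- .softmax_rows(sweep(logc + noise, 2, day_shift, `+`))
  w <- spec$scheme$profile_yields
  hl <- sweep(1 / p, 2, w, `*`) # H/L = w_j / p_j
  out <- tibble(protein_id = rownames(centroids) %||% as.character(seq_len(n)))
  hl_tbl <- as_tibble(as.data.frame(hl))
  names(hl_tbl) <- profile_cols(spec$scheme)
  out <- bind_cols(out, hl_tbl)
  out$map_id <- map_id
  out$condition <- condition
  out$replicate <- replicate
  attr(out, "kind") <- "raw_HL"
  out
}

#' Generate a set of replicate control maps with known ground truth
#'
#' Each protein's normalized profile is its compartment centroid perturbed
#' by logistic-normal noise (softmax of Gaussian-perturbed log-centroids)
#' plus a per-day batch shift shared by cognate control/treated replicates,
#' then converted to raw H/L ratios with the scheme's yield weights, so
#' [normalize_map()] recovers the noisy profile exactly.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `map_set`: `maps` (list of raw H/L profile
#'   tibbles), `markers` (tibble `protein_id`, `compartment`), `truth`
#'   (roster with compartment and marker flags), `condition`, `spec`.
#' @export
make_map_set <- function(spec) {
  roster <- .sim_roster(spec)
  centroids <- roster$centroid
  rownames(centroids) <- roster$protein_id
  shifts <- withr::with_seed(
    spec$seed,
    matrix(rnorm(spec$n_control * 5, 0, spec$batch_sd), spec$n_control, 5)
  )
  maps <- lapply(seq_len(spec$n_control), function(r) {
    .sim_one_map(centroids, spec, shifts[r, ],
      noise_seed = spec$seed + 1000L + r,
      map_id = paste0("control_", r), condition = "control", replicate = r
    )
  })
  structure(
    list(
      maps = maps,
      markers = roster[roster$is_marker, c("protein_id", "compartment")],
      truth = roster[, c("protein_id", "compartment", "is_marker")],
      condition = "control", spec = spec, batch_shifts = shifts
    ),
    class = "map_set"
  )
}

#' Generate treated maps with injected translocations
#'
#' Produces the treated arm of a comparative experiment: the same proteins
#' and day-batch shifts as the control maps, independent profile noise, and
#' for each requested translocation a seeded sample of `n` non-marker
#' proteins of the `from` compartment whose treated centroid is the mixture
#' `(1 - lambda) * from + lambda * to`. With no translocations (or
#' `lambda = 0`) the treated maps are a mock experiment: distributionally
#' identical to controls.
#'
#' @param map_set A `map_set` from [make_map_set()].
#' @param spec A [sim_spec()]; defaults to the one stored in `map_set`.
#' @return A `map_set` for the treated condition whose `truth` carries
#'   `moved`, `moved_to` and `lambda` columns.
#' @export
inject_translocations <- function(map_set, spec = map_set$spec) {
  roster <- .sim_roster(spec)
  centroids <- roster$centroid
  rownames(centroids) <- roster$protein_id
  comp <- spec$compartments
  cent_by_comp <- as.matrix(comp[, paste0("c", 1:5)])
  rownames(cent_by_comp) <- comp$compartment
  truth <- roster[, c("protein_id", "compartment", "is_marker")]
  truth$moved <- FALSE
  truth$moved_to <- NA_character_
  truth$lambda <- NA_real_
  tr <- spec$translocations
  if (!is.null(tr) && nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      cand <- which(roster$compartment == tr$from[i] & !roster$is_marker &
        !truth$moved)
      if (length(cand) < tr$n[i]) {
        abort(sprintf(
          "Requested %d movers from '%s' but only %d non-marker proteins available.",
          tr$n[i], tr$from[i], length(cand)
        ))
      }
      sel <- withr::with_seed(
        spec$seed + 5000L + i,
        cand[sample.int(length(cand), tr$n[i])]
      )
      lam <- tr$lambda[i]
      centroids[sel, ] <- (1 - lam) * centroids[sel, , drop = FALSE] +
        lam * matrix(cent_by_comp[tr$to[i], ],
          length(sel), 5,
          byrow = TRUE
        )
      truth$moved[sel] <- TRUE
      truth$moved_to[sel] <- tr$to[i]
      truth$lambda[sel] <- lam
    }
  }
  shifts <- map_set$batch_shifts
  if (spec$n_treated > nrow(shifts)) {
    abort("More treated than control replicates; no cognate days available.")
  }
  maps <- lapply(seq_len(spec$n_treated), function(r) {
    .sim_one_map(centroids, spec, shifts[r, ],
      noise_seed = spec$seed + 2000L + r,
      map_id = paste0("treated_", r), condition = "treated", replicate = r
    )
  })
  structure(
    list(
      maps = maps,
      markers = roster[roster$is_marker, c("protein_id", "compartment")],
      truth = truth, condition = "treated", spec = spec,
      batch_shifts = shifts
    ),
    class = "map_set"
  )
}

#' Generate global-fraction intensity and LFQ tables with ground truth
#'
#' Builds a Group-2 style N/O/C intensity table and a Group-3 style LFQ
#' replicate table consistent with the experiment's ground truth. Each
#' protein's true global shares follow its compartment's organellar release
#' efficiency (`o = release * m`, `n = baseline + (1 - release) * m`,
#' `c = cytosolic_pool`, with `m = 1 - cytosolic_pool - baseline`); the
#' measured fraction intensities are true amounts (mass x share) times a
#' per-fraction run scale, and the realized fraction yields are returned in
#' a scheme so [onc_profiles()] recovers the true shares. A histone block
#' whose summed mass equals the DNA mass implied by the spec's ploidy is
#' appended, making the proteomic-ruler anchor exact. LFQ replicates add
#' seeded log-normal noise and missing-at-low-intensity dropout.
#'
#' @param spec A [sim_spec()].
#' @param copies Optional named vector of ground-truth copy numbers for the
#'   roster proteins; defaults to a seeded log-normal draw.
#' @return List of class `global_sim`: `intensity_tbl` (Group-2 style),
#'   `lfq_tbl` (long, triplicate control/treated with no injected change),
#'   `truth` (copies, molecular weights, true shares, realized histone
#'   intensity share), `scheme` (realized global yields).
#' @export
make_global_fractions <- function(spec, copies = NULL) {
  roster <- .sim_roster(spec)
  comp <- spec$compartments
  n <- nrow(roster)
  mw <- withr::with_seed(
    spec$seed + 11L,
    pmin(pmax(exp(rnorm(n, log(50), 0.5)), 10), 300)
  )
  if (is.null(copies)) {
    copies <- withr::with_seed(
      spec$seed + 12L,
      setNames(exp(rnorm(n, log(1e5), 1)), roster$protein_id)
    )
  }
  copies <- copies[roster$protein_id]
  idx <- match(roster$compartment, comp$compartment)
  rel <- comp$organellar_release[idx]
  nb <- comp$nuclear_baseline[idx]
  cp <- comp$cytosolic_pool[idx]
  m <- 1 - cp - nb
  share_o <- rel * m
  share_n <- nb + (1 - rel) * m
  share_c <- cp

  # histone block: summed mass tied to DNA mass, as the ruler assumes
  dna_mass_g <- spec$haploid_genome_pg * 1e-12 * spec$ploidy
  h_mw <- rep(14, spec$n_histones)
  h_mass_g <- rep(dna_mass_g / spec$n_histones, spec$n_histones)
  h_copies <- h_mass_g * .AVOGADRO / (h_mw * 1000)
  hist_ids <- sprintf("HIST_%02d", seq_len(spec$n_histones))

  ids <- c(roster$protein_id, hist_ids)
  all_mw <- c(mw, h_mw)
  all_copies <- c(unname(copies), h_copies)
  mass_g <- all_copies * all_mw * 1000 / .AVOGADRO
  so <- c(share_o, rep(0.005, spec$n_histones))
  sn <- c(share_n, rep(0.990, spec$n_histones))
  sc <- c(share_c, rep(0.005, spec$n_histones))

  amount <- cbind(N = mass_g * sn, O = mass_g * so, C = mass_g * sc)
  yields <- colSums(amount) / sum(amount)
  run_scale <- withr::with_seed(spec$seed + 13L, exp(rnorm(3, 0, 0.3)))
  intensity <- sweep(amount, 2, run_scale, `*`) * 1e12 # arbitrary MS scale
  intensity_tbl <- tibble(
    protein_id = ids, gene_name = ids, mol_weight_kda = all_mw,
    intensity_N = intensity[, "N"], intensity_O = intensity[, "O"],
    intensity_C = intensity[, "C"],
    msms_N = 5, msms_O = 5, msms_C = 5
  )

  lfq_rows <- tidyr::expand_grid(
    fraction = spec$scheme$global_fractions,
    condition = c("control", "treated"),
    replicate = seq_len(spec$n_control)
  )
  lfq_tbl <- withr::with_seed(spec$seed + 14L, {
    bind_rows(lapply(seq_len(nrow(lfq_rows)), function(k) {
      f <- lfq_rows$fraction[k]
      base <- amount[, f] * 1e12
      noisy <- base * exp(rnorm(length(base), 0, spec$lfq_noise_sd))
      miss <- rep(FALSE, length(base))
      if (spec$dropout_rate > 0) {
        low <- rank(base) <= ceiling(2 * spec$dropout_rate * length(base))
        miss[low] <- runif(sum(low)) < 0.5
      }
      noisy[miss] <- NA_real_
      tibble(
        protein_id = ids, fraction = f,
        condition = lfq_rows$condition[k],
        replicate = lfq_rows$replicate[k], lfq = noisy
      )
    }))
  })

  truth <- tibble(
    protein_id = ids,
    compartment = c(roster$compartment, rep("Histones", spec$n_histones)),
    mol_weight_kda = all_mw, copies = all_copies,
    share_o = so, share_n = sn, share_c = sc
  )
  structure(
    list(
      intensity_tbl = intensity_tbl, lfq_tbl = lfq_tbl, truth = truth,
      histone_ids = hist_ids,
      histone_intensity_share = sum(mass_g[ids %in% hist_ids]) / sum(mass_g),
      scheme = fraction_scheme(
        profile_fractions = spec$scheme$profile_fractions,
        profile_yields = spec$scheme$profile_yields,
        global_fractions = spec$scheme$global_fractions,
        global_yields = yields[spec$scheme$global_fractions]
      )
    ),
    class = "global_sim"
  )
}

#' Serialize a synthetic map as a proteinGroups-dialect table
#'
#' Writes (or returns) a tab-separated table in the MaxQuant dialect so the
#' generator output can be round-tripped through [read_protein_groups()]
#' and the stringency filters.
#'
#' @param map One raw H/L profile tibble from a `map_set`.
#' @param scheme The [fraction_scheme()] used to generate it.
#' @param path Optional output path; when `NULL` the tibble is returned.
#' @param dialect A [pg_dialect()].
#' @return The proteinGroups-style tibble (invisibly when written).
#' @export
as_protein_groups <- function(map, scheme = fraction_scheme(), path = NULL,
                              dialect = pg_dialect()) {
  out <- tibble(!!dialect$protein_id := map$protein_id)
  out[[dialect$gene_name]] <- map$protein_id
  out[[dialect$mol_weight]] <- 50
  out[[dialect$reverse]] <- ""
  out[[dialect$contaminant]] <- ""
  out[[dialect$only_by_site]] <- ""
  for (f in scheme$profile_fractions) {
    out[[.expand_template(dialect$ratio, f)]] <- map[[paste0("ratio_", f)]]
    out[[.expand_template(dialect$ratio_count, f)]] <- 5
    out[[.expand_template(dialect$ratio_variability, f)]] <- 5
    out[[.expand_template(dialect$msms, f)]] <- 5
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
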