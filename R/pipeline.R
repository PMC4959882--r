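#' Build a static organellar map database from replicate maps
#'
#' Orchestrates the static workflow on already-filtered raw H/L maps:
#' normalize each map, train and apply the marker SVMs per map, combine
#' the replicate classifications, attach percentile scores and confidence
#' classes, optionally Z-filter, compute global N/O/C distributions,
#' proteomic-ruler copy numbers and the organelle mass budget. Layers that
#' lack their inputs (intensities, histones) are skipped.
#'
#' @param maps List of raw H/L profile tibbles (e.g. from
#'   [filter_profile_group()] or a synthetic `map_set$maps`).
#' @param markers Marker tibble `protein_id`, `compartment`.
#' @param scheme A [fraction_scheme()].
#' @param cfg An [svm_config()].
#' @param intensities Optional Group-2 style intensity tibble for the ONC
#'   and abundance layers.
#' @param histone_ids Optional histone ids for the proteomic ruler.
#' @param zfilter_cutoffs Optional named z cut-offs for
#'   [z_filter_reassign()] (applied only when `intensities` are given).
#' @param ruler_args List of extra arguments to [proteomic_ruler()].
#' @param seed Master seed; per-map seeds are derived from it.
#' @return List of class `domap_static`: `normalized` maps, `models`,
#'   `per_map` classifications, `combined` predictions with percentile and
#'   confidence, `loo` accuracies, `onc`, `copies`, `mass`, `zfilter_log`.
#' @export
run_static <- function(maps, markers, scheme = fraction_scheme(),
                       cfg = svm_config(), intensities = NULL,
                       histone_ids = NULL, zfilter_cutoffs = NULL,
                       ruler_args = list(), seed = 1L) {
  if (length(maps) < 1) abort("Need at least one map.")
  normalized <- lapply(maps, normalize_map, scheme = scheme)
  models <- list()
  per_map <- list()
  loo <- list()
  for (i in seq_along(maps)) {
    models[[i]] <- train_svm(maps[[i]], markers, scheme, cfg, seed = seed + i)
    per_map[[i]] <- classify_map(models[[i]], maps[[i]],
      map_id = as.character(i)
    )
    loo[[i]] <- loo_marker_accuracy(maps[[i]], markers, models[[i]])
  }
  combined <- combine_maps(per_map)
  combined <- percentile_and_confidence(combined, markers)

  onc <- NULL
  copies <- NULL
  mass <- NULL
  zlog <- NULL
  if (!is.null(intensities)) {
    onc <- onc_profiles(intensities, scheme)
    if (!is.null(zfilter_cutoffs)) {
      zres <- z_filter_reassign(combined, onc, markers, cutoffs = zfilter_cutoffs)
      combined <- zres$predictions
      zlog <- zres$log
    }
    if (!is.null(histone_ids)) {
      ruler_in <- inner_join(
        select(intensities, "protein_id", "mol_weight_kda"),
        select(onc, "protein_id", intensity_whole = "whole_cell"),
        by = "protein_id"
      )
      copies <- do.call(proteomic_ruler, c(
        list(
          tbl = ruler_in,
          intensity_cols = "intensity_whole", histone_ids = histone_ids
        ),
        ruler_args
      ))
      mass_in <- copies |>
        select("protein_id", "copies", "mol_weight_kda") |>
        inner_join(
          select(onc, "protein_id", "share_o", "share_n", "share_c", "global_class"),
          by = "protein_id"
        ) |>
        left_join(
          select(combined, "protein_id", "top_prediction"),
          by = "protein_id"
        )
      mass <- mass_model(mass_in)
    }
  }
  structure(
    list(
      normalized = normalized, models = models, per_map = per_map,
      combined = combined, loo = loo, onc = onc, copies = copies,
      mass = mass, zfilter_log = zlog, scheme = scheme, seed = seed
    ),
    class = "domap_static"
  )
}

#' Run a comparative (dynamic) organellar map experiment
#'
#' Executes the three branches of the comparative workflow on cognate
#' control/treated map sets: the MR translocation test (with SVM
#' re-localization of the hits), the LFQ global pool comparison, and the
#' copy-number / compartment-flux layer, then merges them into one
#' per-protein report.
#'
#' @param control,treated Lists of raw H/L profile tibbles (equal length,
#'   cognate order).
#' @param markers Marker tibble.
#' @param scheme A [fraction_scheme()].
#' @param cfg An [svm_config()].
#' @param mode,m_cut,r_cut MR combination mode and cut-offs, see
#'   [detect_translocations()].
#' @param lfq Optional long LFQ tibble for [lfq_compare()].
#' @param intensities_before,intensities_after Optional Group-2 intensity
#'   tibbles for the global distribution/flux layers.
#' @param histone_ids Optional histone ids for copy numbers.
#' @param seed Master seed.
#' @return List of class `domap_dynamic`: `mr` (MR table with `significant`
#'   flag), `hits`, `predictions_before`, `predictions_after`,
#'   `global_changes`, `flux`, `copies`.
#' @export
run_dynamic <- function(control, treated, markers, scheme = fraction_scheme(),
                        cfg = svm_config(), mode = "stringent",
                        m_cut = 2, r_cut = 0.9, lfq = NULL,
                        intensities_before = NULL, intensities_after = NULL,
                        histone_ids = NULL, seed = 1L) {
  if (length(control) != length(treated)) {
    abort("Unbalanced replicate counts between conditions.")
  }
  norm_c <- lapply(control, normalize_map, scheme = scheme)
  norm_t <- lapply(treated, normalize_map, scheme = scheme)
  mr <- detect_translocations(norm_c, norm_t, scheme,
    mode = mode,
    m_cut = m_cut, r_cut = r_cut, seed = seed
  )
  hits <- mr$protein_id[mr$significant]

  classify_set <- function(maps, offset) {
    res <- lapply(seq_along(maps), function(i) {
      model <- train_svm(maps[[i]], markers, scheme, cfg, seed = seed + offset + i)
      classify_map(model, maps[[i]], map_id = as.character(i))
    })
    percentile_and_confidence(combine_maps(res), markers)
  }
  pred_before <- classify_set(control, 100L)
  pred_after <- classify_set(treated, 200L)

  onc_before <- if (!is.null(intensities_before)) {
    onc_profiles(intensities_before, scheme)
  }
  onc_after <- if (!is.null(intensities_after)) {
    onc_profiles(intensities_after, scheme)
  }
  global_changes <- if (!is.null(lfq) && !is.null(onc_before)) {
    lfq_compare(lfq, onc_before, onc_after, scheme, seed = seed)
  }
  copies <- NULL
  flux <- NULL
  if (!is.null(onc_before) && !is.null(histone_ids)) {
    ruler_in <- inner_join(
      select(intensities_before, "protein_id", "mol_weight_kda"),
      select(onc_before, "protein_id", intensity_whole = "whole_cell"),
      by = "protein_id"
    )
    copies <- proteomic_ruler(ruler_in,
      intensity_cols = "intensity_whole",
      histone_ids = histone_ids
    )
    if (!is.null(onc_after)) {
      flux <- compartment_flux(copies, onc_before, onc_after)
    }
  }
  report <- mr |>
    left_join(
      select(pred_before,
        "protein_id",
        prediction_before = "top_prediction", score_before = "top_score"
      ),
      by = "protein_id"
    ) |>
    left_join(
      select(pred_after,
        "protein_id",
        prediction_after = "top_prediction", score_after = "top_score"
      ),
      by = "protein_id"
    )
  structure(
    list(
      mr = mr, hits = hits, report = report,
      predictions_before = pred_before, predictions_after = pred_after,
      onc_before = onc_before, onc_after = onc_after,
      global_changes = global_changes, copies = copies, flux = flux,
      scheme = scheme, seed = seed
    ),
    class = "domap_dynamic"
  )
}

#' Write a result bundle as TSV files
#'
#' Persists every tabular layer of a [run_static()] or [run_dynamic()]
#' bundle under a directory, one TSV per layer, with stable column order,
#' so stages can be inspected or re-run in isolation and reruns can be
#' compared byte for byte.
#'
#' @param bundle A `domap_static` or `domap_dynamic` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(tbl, name) {
    if (is.null(tbl) || !is.data.frame(tbl) || nrow(tbl) == 0) {
      return(invisible(NULL))
    }
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(bundle, "domap_static")) {
    for (i in seq_along(bundle$normalized)) {
      emit(bundle$normalized[[i]], sprintf("normalized_map_%d", i))
    }
    emit(bundle$combined, "predictions")
    emit(bundle$onc, "onc_profiles")
    emit(bundle$copies, "copy_table")
    if (!is.null(bundle$mass)) emit(bundle$mass$by_compartment, "mass_budget")
    emit(bundle$zfilter_log, "zfilter_log")
  } else if (inherits(bundle, "domap_dynamic")) {
    emit(as_tibble(bundle$report), "mr_report")
    emit(bundle$global_changes, "global_changes")
    emit(bundle$flux, "compartment_flux")
    emit(bundle$copies, "copy_table")
  } else {
    abort("Not a domapr result bundle.")
  }
  invisible(paths)
}
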