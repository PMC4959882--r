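#' SVM hyper-parameter configuration
#'
#' Grid for the RBF-kernel support vector machines used to classify
#' proteins into compartments. `sigma` is the kernel width in
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; `C` the misclassification
#' penalty. Defaults span the range of optima typically found on
#' log-ratio organellar map data (sigma 0.22-0.48, C 8-35).
#'
#' @param sigma_grid Positive kernel widths to scan.
#' @param c_grid Positive misclassification penalties to scan.
#' @param cv_folds Number of stratified cross-validation folds (default 16).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(sigma_grid = c(0.25, 0.35, 0.5),
                       c_grid = c(8, 16, 32),
                       cv_folds = 16) {
  if (length(sigma_grid) == 0 || any(sigma_grid <= 0)) {
    abort("`sigma_grid` must be non-empty and positive.")
  }
  if (length(c_grid) == 0 || any(c_grid <= 0)) {
    abort("`c_grid` must be non-empty and positive.")
  }
  structure(
    list(sigma_grid = sigma_grid, c_grid = c_grid, cv_folds = cv_folds),
    class = "svm_config"
  )
}

# marker design matrix: log-transformed ratios for labelled proteins
.marker_xy <- function(map, markers, scheme, log_input) {
  m <- profile_matrix(map, scheme)
  if (log_input) {
    if (any(m <= 0)) abort("Ratios must be positive for log transform.")
    m <- log(m)
  }
  idx <- match(markers$protein_id, rownames(m))
  present <- !is.na(idx)
  x <- m[idx[present], , drop = FALSE]
  y <- markers$compartment[present]
  list(x = x, y = y)
}

# one binary one-vs-rest RBF SVM per compartment; decision value oriented
# so that class members score positive
.fit_ovr <- function(x, y, compartments, sigma, C) {
  kpar <- list(sigma = 1 / (2 * sigma^2))
  lapply(setNames(compartments, compartments), function(comp) {
    lab <- factor(ifelse(y == comp, "member", "rest"), levels = c("member", "rest"))
    fit <- kernlab::ksvm(
      x = x, y = lab, type = "C-svc", kernel = "rbfdot",
      kpar = kpar, C = C, scaled = FALSE
    )
    dec <- kernlab::predict(fit, x, type = "decision")[, 1]
    flip <- mean(dec[lab == "member"]) < mean(dec[lab == "rest"])
    list(fit = fit, flip = flip)
  })
}

.decision_matrix <- function(models, x) {
  cols <- lapply(models, function(m) {
    dec <- kernlab::predict(m$fit, x, type = "decision")[, 1]
    if (m$flip) -dec else dec
  })
  do.call(cbind, cols)
}

# stratified fold assignment, seeded, deterministic
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (comp in unique(y)) {
      idx <- which(y == comp)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Train marker-based organellar SVM classifiers for one map
#'
#' Log-transforms the fractionation profiles of the marker proteins and
#' grid-searches the RBF width sigma and penalty C by stratified k-fold
#' cross-validation, minimizing the overall marker misclassification rate
#' (ties broken toward smaller C, then smaller sigma). The final model is a
#' set of one-vs-rest binary SVMs, one per compartment, refit on all
#' markers at the chosen parameters; proteins are assigned to the
#' compartment with the highest decision value.
#'
#' @param map A profile tibble (raw H/L ratios; `log_input = TRUE` applies
#'   the log transform).
#' @param markers Tibble `protein_id`, `compartment`.
#' @param scheme A [fraction_scheme()].
#' @param cfg An [svm_config()].
#' @param seed Seed for fold assignment.
#' @param log_input Log-transform the ratio matrix before training.
#' @return An object of class `organelle_svm`.
#' @export
train_svm <- function(map, markers, scheme = fraction_scheme(),
                      cfg = svm_config(), seed = 1L, log_input = TRUE) {
  xy <- .marker_xy(map, markers, scheme, log_input)
  counts <- table(xy$y)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(paste0(
      "Compartment(s) with fewer than 2 markers in the map: ",
      paste(small, collapse = ", ")
    ))
  }
  compartments <- sort(unique(xy$y))
  k <- min(cfg$cv_folds, nrow(xy$x))
  folds <- .stratified_folds(xy$y, k, seed)

  grid <- tidyr::expand_grid(sigma = cfg$sigma_grid, C = cfg$c_grid)
  grid$cv_error <- purrr::map2_dbl(grid$sigma, grid$C, function(sig, C) {
    wrong <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(xy$y[tr])) < length(compartments)) next
      models <- .fit_ovr(xy$x[tr, , drop = FALSE], xy$y[tr], compartments, sig, C)
      dec <- .decision_matrix(models, xy$x[!tr, , drop = FALSE])
      pred <- compartments[max.col(dec, ties.method = "first")]
      wrong <- wrong + sum(pred != xy$y[!tr])
    }
    wrong / length(xy$y)
  })
  best <- arrange(grid, .data$cv_error, .data$C, .data$sigma)[1, ]
  models <- .fit_ovr(xy$x, xy$y, compartments, best$sigma, best$C)
  structure(
    list(
      models = models, sigma = best$sigma, C = best$C,
      cv_error = best$cv_error, grid = grid, compartments = compartments,
      scheme = scheme, log_input = log_input,
      n_markers = length(xy$y), folds = k, seed = seed
    ),
    class = "organelle_svm"
  )
}

#' @export
print.organelle_svm <- function(x, ...) {
  cat(sprintf(
    "<organelle_svm> %d compartments, %d markers; sigma = %.3g, C = %.3g, CV error = %.3f\n",
    length(x$compartments), x$n_markers, x$sigma, x$C, x$cv_error
  ))
  invisible(x)
}

#' @export
tidy.organelle_svm <- function(x, ...) x$grid

#' @export
glance.organelle_svm <- function(x, ...) {
  tibble(
    sigma = x$sigma, C = x$C, cv_error = x$cv_error,
    n_markers = x$n_markers, n_compartments = length(x$compartments),
    cv_folds = x$folds
  )
}

#' Classify all proteins of a map
#'
#' Computes the one-vs-rest decision score of every protein for every
#' compartment. Positive scores indicate class membership (the protein
#' falls inside that compartment's boundary); the class with the highest
#' score is the top prediction even if all scores are negative, in which
#' case the assignment is a nearest-cluster best guess.
#'
#' @param model An `organelle_svm` from [train_svm()].
#' @param map A profile tibble on the same fraction scheme.
#' @param map_id Optional label attached to the result.
#' @return A classification tibble: `protein_id`, `map_id`, one
#'   `score_<compartment>` column per class, `top_prediction`, `top_score`;
#'   attribute `cumulative = FALSE`.
#' @export
classify_map <- function(model, map, map_id = NA_character_) {
  m <- profile_matrix(map, model$scheme)
  if (ncol(m) != length(model$scheme$profile_fractions)) {
    abort("Map dimensionality does not match the trained model.")
  }
  if (model$log_input) {
    if (any(m <= 0)) abort("Ratios must be positive for log transform.")
    m <- log(m)
  }
  dec <- .decision_matrix(model$models, m)
  top <- max.col(dec, ties.method = "first")
  scores <- as_tibble(as.data.frame(dec))
  names(scores) <- paste0("score_", model$compartments)
  out <- bind_cols(
    tibble(protein_id = map$protein_id, map_id = map_id),
    scores
  )
  out$top_prediction <- model$compartments[top]
  out$top_score <- dec[cbind(seq_len(nrow(dec)), top)]
  attr(out, "cumulative") <- FALSE
  attr(out, "compartments") <- model$compartments
  out
}

#' Leave-one-out marker classification accuracy
#'
#' Re-fits the one-vs-rest SVMs once per marker with that marker held out
#' (at the hyper-parameters chosen by [train_svm()]) and predicts the
#' held-out marker; this simulates the prediction of proteins outside the
#' training set. Reports overall percent correct, a per-compartment table,
#' and their unweighted average.
#'
#' @param map Profile tibble.
#' @param markers Marker tibble.
#' @param model A trained `organelle_svm` (supplies sigma, C, scheme).
#' @return List of class `loo_accuracy`: `overall` (percent),
#'   `average_per_compartment` (unweighted mean of per-class percents),
#'   `by_compartment` tibble, and `predictions` (held-out classification
#'   tibble with score columns).
#' @export
loo_marker_accuracy <- function(map, markers, model) {
  xy <- .marker_xy(map, markers, model$scheme, model$log_input)
  n <- nrow(xy$x)
  compartments <- model$compartments
  dec_all <- matrix(NA_real_, n, length(compartments),
    dimnames = list(rownames(xy$x), compartments)
  )
  for (i in seq_len(n)) {
    models <- .fit_ovr(
      xy$x[-i, , drop = FALSE], xy$y[-i], compartments,
      model$sigma, model$C
    )
    dec_all[i, ] <- .decision_matrix(models, xy$x[i, , drop = FALSE])
  }
  top <- max.col(dec_all, ties.method = "first")
  pred <- compartments[top]
  by_comp <- tibble(compartment = xy$y, correct = pred == xy$y) |>
    group_by(.data$compartment) |>
    summarise(
      n = n(), n_correct = sum(.data$correct),
      pct_correct = 100 * mean(.data$correct), .groups = "drop"
    )
  scores <- as_tibble(as.data.frame(dec_all))
  names(scores) <- paste0("score_", compartments)
  predictions <- bind_cols(
    tibble(
      protein_id = rownames(xy$x), compartment = xy$y,
      top_prediction = pred,
      top_score = dec_all[cbind(seq_len(n), top)]
    ),
    scores
  )
  attr(predictions, "cumulative") <- FALSE
  attr(predictions, "compartments") <- compartments
  structure(
    list(
      overall = 100 * mean(pred == xy$y),
      average_per_compartment = mean(by_comp$pct_correct),
      by_compartment = by_comp, predictions = predictions
    ),
    class = "loo_accuracy"
  )
}

#' @export
print.loo_accuracy <- function(x, ...) {
  cat(sprintf(
    "<loo_accuracy> overall %.1f%% correct; average per compartment %.1f%%\n",
    x$overall, x$average_per_compartment
  ))
  print(x$by_compartment)
  invisible(x)
}
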