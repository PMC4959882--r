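sc <- fraction_scheme()

# shared fixture: one synthetic map set with well-separated compartments
spec5 <- small_sim_spec(seed = 31L)
ms5 <- make_map_set(spec5)

test_that("separable clusters reach zero CV error and training is deterministic", {
  model <- train_svm(ms5$maps[[1]], ms5$markers, sc, seed = 2L)
  expect_equal(model$cv_error, 0)
  model2 <- train_svm(ms5$maps[[1]], ms5$markers, sc, seed = 2L)
  expect_equal(glance(model2), glance(model))
  res1 <- classify_map(model, ms5$maps[[1]])
  res2 <- classify_map(model2, ms5$maps[[1]])
  expect_equal(res1, res2)
  expect_error(
    train_svm(ms5$maps[[1]],
      ms5$markers[!duplicated(ms5$markers$compartment), ], sc
    ),
    "fewer than 2 markers"
  )
})

test_that("well-separated synthetic compartments classify to >= 95% accuracy", {
  model <- train_svm(ms5$maps[[1]], ms5$markers, sc, seed = 1L)
  expect_lte(model$cv_error, 0.05)
  res <- classify_map(model, ms5$maps[[1]])
  # totality: every protein gets exactly one top prediction
  expect_equal(nrow(res), nrow(ms5$maps[[1]]))
  expect_true(all(res$top_prediction %in% model$compartments))
  # markers recover their own class
  mk <- dplyr::inner_join(res, ms5$markers, by = "protein_id")
  expect_gte(mean(mk$top_prediction == mk$compartment), 0.95)
  # non-marker proteins recover ground truth
  truth <- dplyr::inner_join(res, ms5$truth, by = "protein_id")
  expect_gte(mean(truth$top_prediction == truth$compartment), 0.9)
})

test_that("a protein at a cluster centroid scores positive for that class", {
  spec0 <- small_sim_spec(seed = 32L, noise_sd = 0.05)
  ms <- make_map_set(spec0)
  model <- train_svm(ms$maps[[1]], ms$markers, sc, seed = 1L)
  # centroid proteins: rebuild noiseless map rows
  spec_noiseless <- small_sim_spec(seed = 32L, noise_sd = 0)
  center_map <- make_map_set(spec_noiseless)$maps[[1]]
  res <- classify_map(model, center_map)
  truth <- dplyr::inner_join(res, ms$truth, by = "protein_id")
  own_score <- vapply(seq_len(nrow(truth)), function(i) {
    truth[[paste0("score_", truth$compartment[i])]][i]
  }, numeric(1))
  expect_gte(mean(own_score > 0), 0.99)
})

test_that("leave-one-out accuracy is near-perfect on separable markers and bookkeeping is exact", {
  model <- train_svm(ms5$maps[[1]], ms5$markers, sc, seed = 1L)
  loo <- loo_marker_accuracy(ms5$maps[[1]], ms5$markers, model)
  expect_gte(loo$overall, 95)
  expect_equal(
    loo$overall,
    100 * sum(loo$by_compartment$n_correct) / sum(loo$by_compartment$n)
  )
  expect_equal(
    loo$average_per_compartment,
    mean(loo$by_compartment$pct_correct)
  )
})

test_that("accuracy degrades as cluster overlap increases", {
  acc <- vapply(c(0.05, 0.3, 0.8), function(nsd) {
    spec <- small_sim_spec(seed = 33L, noise_sd = nsd, n_proteins = 14, n_markers = 14)
    ms <- make_map_set(spec)
    model <- train_svm(ms$maps[[1]], ms$markers, sc,
      cfg = svm_config(sigma_grid = 0.35, c_grid = 16), seed = 1L
    )
    loo_marker_accuracy(ms$maps[[1]], ms$markers, model)$overall
  }, numeric(1))
  expect_true(acc[1] >= acc[2] - 2 && acc[2] >= acc[3] - 2)
  expect_gt(acc[1], acc[3])
})

test_that("combining maps sums positive scores and rewards consistency", {
  s1 <- rbind(c(0.5, -0.2))
  colnames(s1) <- c("ER", "Golgi")
  s2 <- rbind(c(0.3, 0.1))
  colnames(s2) <- c("ER", "Golgi")
  r1 <- manual_classification("P1", s1, "1")
  r2 <- manual_classification("P1", s2, "2")
  comb <- combine_maps(list(r1, r2))
  expect_equal(comb$score_ER, 0.8)
  expect_equal(comb$score_Golgi, 0.1)
  expect_equal(comb$top_prediction, "ER")
  # single input: negatives floored for ranking
  single <- combine_maps(list(r1))
  expect_equal(single$score_Golgi, 0)
  expect_equal(single$score_ER, 0.5)
  # six medium scores outrank one strong score
  medium <- manual_classification("P2", rbind(c(0.4, 0.1)) |>
    `colnames<-`(c("ER", "Golgi")), "m")
  strong <- manual_classification("P3", rbind(c(1.5, 0.0)) |>
    `colnames<-`(c("ER", "Golgi")), "s")
  six <- combine_maps(c(rep(list(medium), 6), list(strong)))
  expect_gt(
    six$score_ER[six$protein_id == "P2"],
    six$score_ER[six$protein_id == "P3"]
  )
})

test_that("combining is permutation-invariant and additive at the score level", {
  withr::with_seed(9, {
    results <- lapply(1:4, function(i) {
      s <- matrix(rnorm(20 * 3), 20, 3)
      colnames(s) <- c("ER", "Golgi", "Mito")
      manual_classification(paste0("P", 1:20), s, as.character(i))
    })
  })
  ab <- combine_maps(results)
  ba <- combine_maps(rev(results))
  expect_equal(
    ab[order(ab$protein_id), ],
    ba[order(ba$protein_id), ]
  )
  score_cols <- paste0("score_", c("ER", "Golgi", "Mito"))
  part1 <- combine_maps(results[1:2])
  part2 <- combine_maps(results[3:4])
  whole <- ab[order(ab$protein_id), score_cols]
  pieces <- (part1[order(part1$protein_id), score_cols] +
    part2[order(part2$protein_id), score_cols])
  expect_equal(as.data.frame(whole), as.data.frame(pieces), ignore_attr = TRUE)
})

test_that("percentile scores use correctly predicted markers and map to confidence bands", {
  n <- 200
  scores <- cbind(ER = as.numeric(1:n), Golgi = rep(0, n))
  res <- manual_classification(paste0("M", 1:n), scores)
  attr(res, "cumulative") <- TRUE
  markers <- tibble::tibble(
    protein_id = paste0("M", 1:n),
    compartment = "ER"
  )
  out <- percentile_and_confidence(res, markers)
  # score at the marker median -> percentile 50
  med_row <- which.min(abs(out$top_score - median(out$top_score)))
  expect_equal(out$percentile[med_row], 50, tolerance = 1)
  # monotone in score
  expect_true(all(diff(out$percentile[order(out$top_score)]) >= 0))
  # confidence bands
  expect_equal(
    unname(out$confidence_class[out$percentile == 30]), "High"
  )
  expect_equal(
    unname(out$confidence_class[out$percentile == 0.5]), "Very low"
  )
  expect_equal(unname(out$confidence_class[out$percentile == 2]), "Low")
  expect_equal(unname(out$confidence_class[out$percentile == 10]), "Medium")
  expect_equal(unname(out$confidence_class[out$percentile == 60]), "Very High")
  # no correctly predicted markers -> error
  bad_markers <- tibble::tibble(
    protein_id = paste0("M", 1:n),
    compartment = "Golgi"
  )
  expect_error(percentile_and_confidence(res, bad_markers), "No correctly")
})

test_that("subcompartment prediction works within a parent and limits the label set", {
  # ER proteins get two synthetic subcompartments along fraction 4 vs 5
  spec <- small_sim_spec(seed = 35L, noise_sd = 0.08)
  ms <- make_map_set(spec)
  er_ids <- ms$truth$protein_id[ms$truth$compartment == "ER"]
  half <- seq_along(er_ids) %% 2 == 0
  # build maps where the two halves are separated
  maps <- lapply(ms$maps, function(m) {
    rows <- match(er_ids[half], m$protein_id)
    m$ratio_24K[rows] <- m$ratio_24K[rows] * 3
    m
  })
  preds <- manual_classification(
    ms$truth$protein_id,
    {
      s <- cbind(ER = ifelse(ms$truth$compartment == "ER", 1, -1), Other = 0)
      s
    }
  )
  submk <- tibble::tibble(
    protein_id = er_ids[c(which(!half)[1:8], which(half)[1:8])],
    compartment = rep(c("Lumen", "Membrane"), each = 8)
  )
  subres <- predict_subcompartments(maps, preds, submk, "ER",
    sc,
    cfg = svm_config(sigma_grid = 0.35, c_grid = 16), seed = 1L
  )
  expect_true(all(
    subres$combined$top_prediction %in% c("Lumen", "Membrane")
  ))
  loo_overall <- mean(vapply(subres$loo, function(l) l$overall, numeric(1)))
  expect_gte(loo_overall, 95)
  # a submarker outside the parent is excluded with a warning
  submk_bad <- dplyr::bind_rows(
    submk,
    tibble::tibble(protein_id = "NOT_ER", compartment = "Lumen")
  )
  expect_warning(
    predict_subcompartments(maps, preds, submk_bad, "ER", sc,
      cfg = svm_config(sigma_grid = 0.35, c_grid = 16), seed = 1L
    ),
    "excluded"
  )
})

test_that("Z-filtering re-assigns outliers by the robust ONB rule", {
  # markers with log2 ONB median -3 and MAD 0.5; protein at -7 has z ~ 5.39
  mk_onb <- c(-4, -3.5, -3, -2.5, -2)
  mk_ids <- paste0("NPCM", seq_along(mk_onb))
  markers <- tibble::tibble(
    protein_id = mk_ids,
    compartment = "Nuclear pore complex"
  )
  eps <- 1e-4
  onb_to_shares <- function(l2) {
    ratio <- 2^l2
    tibble::tibble(share_o = ratio * (0.5 + eps) - eps, share_n = 0.5)
  }
  # verify the helper inverts the pseudocounted ratio
  shares <- onb_to_shares(c(mk_onb, -7, -3))
  expect_equal(
    log2((shares$share_o + eps) / (shares$share_n + eps)),
    c(mk_onb, -7, -3),
    tolerance = 1e-6
  )
  onc <- dplyr::bind_cols(
    tibble::tibble(protein_id = c(mk_ids, "FAR", "NEAR")),
    shares
  )
  scores <- cbind(
    `Nuclear pore complex` = rep(1, 7),
    ER = c(rep(0.5, 6), -0.2),
    Golgi = rep(-1, 7)
  )
  preds <- manual_classification(c(mk_ids, "FAR", "NEAR"), scores)
  attr(preds, "cumulative") <- TRUE
  res <- z_filter_reassign(preds, onc, markers,
    cutoffs = c("Nuclear pore complex" = 5)
  )
  lg <- res$log
  z_far <- lg$z[lg$protein_id == "FAR"]
  expect_equal(z_far, (-3 - (-7)) / (0.5 * 1.483), tolerance = 1e-3)
  expect_true(z_far > 5)
  expect_equal(
    res$predictions$top_prediction[res$predictions$protein_id == "FAR"],
    "ER"
  )
  # protein at the marker median keeps its class with z ~ 0
  expect_equal(lg$z[lg$protein_id == "NEAR"], 0, tolerance = 1e-3)
  expect_equal(
    res$predictions$top_prediction[res$predictions$protein_id == "NEAR"],
    "Nuclear pore complex"
  )
  # no positive second class: kept with fallback logged
  scores2 <- scores
  scores2[7, "ER"] <- -0.2
  preds2 <- manual_classification(c(mk_ids, "FAR", "NEAR"), scores2)
  attr(preds2, "cumulative") <- TRUE
  onc2 <- onc
  onc2[onc2$protein_id == "FAR", c("share_o", "share_n")] <-
    onb_to_shares(-3)[, c("share_o", "share_n")]
  onc2[onc2$protein_id == "NEAR", c("share_o", "share_n")] <-
    onb_to_shares(-7)[, c("share_o", "share_n")]
  res2 <- z_filter_reassign(preds2, onc2, markers,
    cutoffs = c("Nuclear pore complex" = 5)
  )
  lg2 <- res2$log
  expect_true(lg2$kept_by_fallback[lg2$protein_id == "NEAR"])
  expect_equal(
    res2$predictions$top_prediction[res2$predictions$protein_id == "NEAR"],
    "Nuclear pore complex"
  )
})
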