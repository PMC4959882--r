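sc <- fraction_scheme()
dcols <- paste0("delta_", sc$profile_fractions)

delta_tbl <- function(m, ids = paste0("P", seq_len(nrow(m)))) {
  out <- tibble::tibble(protein_id = ids)
  for (j in seq_along(dcols)) out[[dcols[j]]] <- m[, j]
  out
}

test_that("MCD equals exhaustive h-subset enumeration on seeded toy data", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(9:12, 1)
      x <- matrix(rnorm(n * 2), n, 2)
      # a couple of gross outliers
      x[1:2, ] <- x[1:2, ] + 6
    })
    want <- oracle_mcd(x, alpha = 0.9)
    # exact enumeration path
    fit <- mcd_estimate(x, alpha = 0.9, seed = 1L)
    expect_equal(fit$best, want$best)
    expect_equal(fit$center, want$center, tolerance = 1e-12)
    expect_equal(fit$cov_raw, want$cov_raw, tolerance = 1e-12)
    expect_equal(mcd_distances(fit, x, scaled = FALSE), want$dist,
      tolerance = 1e-9
    )
    # seeded C-step search path finds the same optimum
    fit2 <- mcd_estimate(x, alpha = 0.9, seed = 7L, exact_limit = 0)
    expect_equal(fit2$best, want$best)
  }
})

test_that("MCD location agrees with an independent robust estimator on contaminated data", {
  skip_if_not_installed("MASS")
  withr::with_seed(99, {
    x <- rbind(
      matrix(rnorm(180 * 3), 180, 3),
      matrix(rnorm(20 * 3, mean = 8), 20, 3)
    )
  })
  fit <- mcd_estimate(x, alpha = 0.75, seed = 1L)
  ref <- MASS::cov.rob(x, method = "mcd", quantile.used = floor(0.75 * 200))
  expect_equal(fit$center, ref$center, tolerance = 0.15, ignore_attr = TRUE)
  # both reject the shifted block
  expect_true(all(fit$center < 1))
})

test_that("BH adjustment matches the direct step-up reference", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  withr::with_seed(123, {
    for (i in 1:50) {
      p <- runif(sample(5:200, 1))^sample(1:3, 1)
      expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("M scores: null rows score zero, outliers score high, BH bounds hold", {
  withr::with_seed(11, {
    noise <- matrix(rnorm(400 * 5, 0, 0.02), 400, 5)
    noise <- noise - rowMeans(noise)
  })
  noise[1, ] <- 0 # an exactly-null delta profile
  noise[2, ] <- c(-0.4, 0.4, 0, 0, 0) # a strong mover
  d <- delta_tbl(noise)
  ms <- m_scores(d, sc, seed = 1L)
  expect_lt(ms$distance[1], qchisq(0.5, 5))
  expect_equal(ms$m[1], 0, tolerance = 0.05)
  expect_gt(ms$m[2], 5)
  # Q monotone in p and bounded below by p
  expect_true(all(ms$q_value >= ms$p_value - 1e-12))
  o <- order(ms$p_value)
  expect_true(all(diff(ms$q_value[o]) >= -1e-12))
})

test_that("M is invariant to row permutation and to a common location shift", {
  withr::with_seed(12, {
    x <- matrix(rnorm(300 * 5, 0, 0.05), 300, 5)
    x <- x - rowMeans(x)
  })
  d <- delta_tbl(x)
  ms <- m_scores(d, sc, seed = 3L)
  perm <- withr::with_seed(1, sample(300))
  ms_perm <- m_scores(delta_tbl(x[perm, ], ids = paste0("P", perm)), sc, seed = 3L)
  expect_equal(
    ms_perm$m[match(ms$protein_id, ms_perm$protein_id)], ms$m,
    tolerance = 1e-6
  )
  shift <- matrix(rep(c(0.1, -0.05, 0.02, -0.04, -0.03), each = 300), 300, 5)
  ms_shift <- m_scores(delta_tbl(x + shift), sc, seed = 3L)
  expect_equal(ms_shift$distance, ms$distance, tolerance = 1e-6)
})

test_that("null chi-square p-values are stochastically no smaller than uniform", {
  pool <- unlist(lapply(1:20, function(rep) {
    withr::with_seed(2000 + rep, {
      x <- matrix(rnorm(2000 * 5, 0, 0.03), 2000, 5)
      x <- x - rowMeans(x)
    })
    m_scores(delta_tbl(x), sc, seed = rep)$p_value
  }))
  # one-sided KS: evidence that p-values are smaller than uniform?
  ks <- suppressWarnings(stats::ks.test(pool, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.001)
})

test_that("R scores are pairwise Pearson correlations of delta profiles", {
  base <- rbind(c(0.3, -0.3, 0, 0, 0), c(0.1, 0.1, -0.2, 0, 0))
  d1 <- delta_tbl(base, ids = c("A", "B"))
  d2 <- delta_tbl(base, ids = c("A", "B"))
  d3 <- delta_tbl(-base, ids = c("A", "B"))
  rs <- r_scores(list(d1, d2, d3), sc)
  expect_equal(sort(unique(rs$pair)), c("1:2", "1:3", "2:3"))
  expect_equal(rs$r[rs$pair == "1:2"], c(1, 1))
  expect_equal(rs$r[rs$pair == "1:3"], c(-1, -1))
  # zero-variance profile -> NA
  dz <- delta_tbl(rbind(c(0, 0, 0, 0, 0)), ids = "Z")
  dz2 <- delta_tbl(rbind(c(0.1, -0.1, 0, 0, 0)), ids = "Z")
  rz <- r_scores(list(dz, dz2), sc)
  expect_true(is.na(rz$r))
  # independent noise: mean correlation near zero
  withr::with_seed(13, {
    da <- delta_tbl(matrix(rnorm(1000 * 5), 1000, 5))
    db <- delta_tbl(matrix(rnorm(1000 * 5), 1000, 5))
  })
  rn <- r_scores(list(da, db), sc)
  expect_lt(abs(mean(rn$r)), 0.1)
})

test_that("MR combination takes minima (stringent) or medians (sensitive)", {
  m_tbl <- tibble::tibble(
    protein_id = "P1", pair = c("1", "2", "3"),
    m = c(2.5, 3.0, 2.1)
  )
  r_tbl <- tibble::tibble(
    protein_id = "P1", pair = c("1:2", "1:3", "2:3"),
    r = c(0.95, 0.92, 0.99)
  )
  stringent <- combine_mr(m_tbl, r_tbl, "stringent")
  expect_equal(stringent$m_combined, 2.1)
  expect_equal(stringent$r_combined, 0.92)
  sensitive <- combine_mr(m_tbl, r_tbl, "sensitive")
  expect_equal(sensitive$m_combined, 2.5)
  expect_equal(sensitive$r_combined, 0.95)
  # duplicate experiment: two M scores, one R score
  dup <- combine_mr(m_tbl[1:2, ], r_tbl[1, ], "stringent")
  expect_equal(dup$m_combined, 2.5)
  expect_equal(dup$r_combined, 0.95)
  expect_setequal(
    setdiff(names(dup), c("protein_id", "m_combined", "r_combined")),
    c("m_1", "m_2", "r_1:2")
  )
})

test_that("depth scaling of the mock FDR reproduces the printed worked example", {
  res <- scale_fdr(3, 3766, 2237, 18)
  expect_equal(res$expected_fp, 3 * 2237 / 3766)
  expect_equal(round(res$expected_fp, 1), 1.8)
  expect_equal(round(100 * res$fdr), 10)
  expect_equal(scale_fdr(0, 1000, 500, 7)$fdr, 0)
  expect_equal(scale_fdr(5, 1000, 1000, 10)$expected_fp, 5)
  expect_warning(res0 <- scale_fdr(2, 1000, 1000, 0), "undefined")
  expect_true(is.na(res0$fdr))
})

test_that("cut-off calibration finds FDR-0 boundaries that empty the mock quadrant", {
  withr::with_seed(21, {
    mock <- tibble::tibble(
      protein_id = paste0("P", 1:500),
      m_combined = runif(500, 0, 1.9), r_combined = runif(500, -0.5, 0.85)
    )
    experiment <- tibble::tibble(
      protein_id = paste0("P", 1:500),
      m_combined = c(runif(490, 0, 1.9), runif(10, 2.5, 4)),
      r_combined = c(runif(490, -0.5, 0.85), runif(10, 0.92, 1))
    )
  })
  class(mock) <- c("mr_scores", class(mock))
  class(experiment) <- c("mr_scores", class(experiment))
  cal <- calibrate_cutoffs(mock, experiment, target_fdr = 0)
  expect_equal(cal$mock_hits, 0)
  expect_equal(cal$fdr, 0)
  # (2, 0.9) is admissible by construction; chosen cuts capture all 10 movers
  expect_lte(cal$m_cut, 2)
  expect_lte(cal$r_cut, 0.9)
  expect_equal(cal$experiment_hits, 10)
  g <- glance(cal)
  expect_equal(g$mock_depth, 500)
  # unattainable target errors with the best achievable rate
  mock_bad <- mock
  mock_bad$m_combined <- experiment$m_combined
  mock_bad$r_combined <- experiment$r_combined
  expect_error(
    calibrate_cutoffs(mock_bad, experiment,
      target_fdr = 0,
      m_grid = 0.1, r_grid = 0.1
    ),
    "unattainable"
  )
})

test_that("identical control and treated maps yield zero hits", {
  spec <- small_sim_spec(seed = 41L, n_proteins = 60)
  ms <- make_map_set(spec)
  norm <- lapply(ms$maps, normalize_map, scheme = sc)
  mr <- detect_translocations(norm, norm, sc, m_cut = 0.1, r_cut = 0)
  expect_equal(sum(mr$significant), 0)
})

test_that("injected movers are recovered and mocks stay empty", {
  tr <- tibble::tibble(from = "Mitochondria", to = "Endosomes", n = 3, lambda = 1)
  spec <- small_sim_spec(seed = 43L, translocations = tr)
  ctrl <- make_map_set(spec)
  trt <- inject_translocations(ctrl)
  norm_c <- lapply(ctrl$maps, normalize_map, scheme = sc)
  norm_t <- lapply(trt$maps, normalize_map, scheme = sc)
  mr <- detect_translocations(norm_c, norm_t, sc, m_cut = 0.6, r_cut = 0.7)
  moved <- trt$truth$protein_id[trt$truth$moved]
  expect_equal(length(moved), 3)
  hits <- mr$protein_id[mr$significant]
  expect_gte(mean(moved %in% hits), 0.9)
  expect_lte(sum(!hits %in% moved), 1)
  # mock: no injection
  spec0 <- small_sim_spec(seed = 44L)
  c0 <- make_map_set(spec0)
  t0 <- inject_translocations(c0)
  mr0 <- detect_translocations(
    lapply(c0$maps, normalize_map, scheme = sc),
    lapply(t0$maps, normalize_map, scheme = sc),
    sc,
    m_cut = 2, r_cut = 0.9
  )
  expect_equal(sum(mr0$significant), 0)
})
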