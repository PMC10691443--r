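test_that("replicate merging follows the mean/single/missing rules", {
  d <- ascending_axis()
  v1 <- matrix(80, 6, 6); v2 <- matrix(90, 6, 6)
  v1[3, 4] <- NA                 # only replicate 2 present
  v2[5, 5] <- NA                 # only replicate 1 present
  v1[2, 2] <- NA; v2[2, 2] <- NA # both missing
  m <- merge_replicates(dose_matrix(v1, d, d, 1, "L", 18, 1),
                        dose_matrix(v2, d, d, 1, "L", 18, 2))
  expect_equal(m$values[1, 1], 85)   # mean where both present
  expect_equal(m$values[3, 4], 90)   # the single available value
  expect_equal(m$values[5, 5], 80)
  expect_true(is.na(m$values[2, 2]))
  d2 <- ascending_axis(1)
  expect_error(merge_replicates(dose_matrix(v1, d, d, 1, "L", 18, 1),
                                dose_matrix(v2, d2, d, 1, "L", 18, 2)),
               "dose vectors")
})

test_that("monotherapy-missing matrices are excluded, interior cells imputed", {
  d <- ascending_axis()
  complete <- matrix(90, 6, 6)
  broken <- complete; broken[4, 1] <- NA       # missing monotherapy well
  u <- apply_missing_rules(dose_matrix(broken, d, d, 1, "L", 18, 1),
                           dose_matrix(complete, d, d, 1, "L", 18, 2))
  expect_length(u, 1)
  expect_equal(u[[1]]$replicate, 2)
  expect_equal(attr(u, "n_excluded"), 1L)
  # interior missing cell: matrix kept, cell imputed with 100% viability
  interior <- complete; interior[3, 4] <- NA
  u2 <- apply_missing_rules(dose_matrix(interior, d, d, 1, "L", 18, 1))
  expect_length(u2, 1)
  expect_equal(u2[[1]]$values[3, 4], 100)
  expect_equal(attr(u2, "n_imputed"), 1L)
  # both replicates complete pass through unchanged
  u3 <- apply_missing_rules(dose_matrix(complete, d, d, 1, "L", 18, 1),
                            dose_matrix(complete, d, d, 1, "L", 18, 2))
  expect_length(u3, 2)
  expect_equal(u3[[1]]$values, complete)
})

test_that("the Hill fit recovers noiseless generating parameters", {
  truth <- list(e0 = 100, emax = 10, ec50 = 0.5, slope = 1.5)
  d <- ascending_axis()
  fit <- fit_monotherapy(d, hill_viability(truth, d))
  rel <- abs(c(fit$e0, fit$emax, fit$ec50, fit$slope) -
               c(100, 10, 0.5, 1.5)) / c(100, 10, 0.5, 1.5)
  expect_lt(max(rel), 1e-3)
  expect_identical(fit$flag, "")
  # midpoint identity of the fitted curve
  expect_equal(hill_viability(fit, fit$ec50), (fit$e0 + fit$emax) / 2)
})

test_that("degenerate monotherapy inputs are flagged, not rejected", {
  d <- ascending_axis()
  flat <- fit_monotherapy(d, rep(100, 6))
  expect_identical(flat$flag, "flat")
  expect_equal(flat$e0, 100)
  expect_equal(flat$emax, 100)
  increasing <- fit_monotherapy(d, c(100, 105, 112, 120, 131, 140))
  expect_identical(increasing$flag, "poor_fit")
  expect_true(is.finite(increasing$ec50))
})

test_that("Bliss and HSA surfaces match cellwise brute force", {
  hA <- list(e0 = 100, emax = 0, ec50 = 0.3, slope = 2)
  hB <- list(e0 = 100, emax = 20, ec50 = 1, slope = 0.8)
  d1 <- ascending_axis(5); d2 <- ascending_axis(1)
  bliss <- bliss_reference(hA, hB, d1, d2)
  hsa <- hsa_reference(hA, hB, d1, d2)
  for (i in seq_along(d1)) for (j in seq_along(d2)) {
    va <- hill_viability(hA, d1[i]); vb <- hill_viability(hB, d2[j])
    expect_identical(bliss[i, j], va * vb / 100)
    expect_identical(hsa[i, j], min(va, vb))
  }
  # margins equal the monotherapy curves when e0 = 100
  expect_equal(bliss[, 1], hill_viability(hA, d1))
  expect_equal(hsa[1, ], hill_viability(hB, d2))
})

test_that("HSA reference dominates Bliss cellwise on random curves", {
  set.seed(14)
  for (rep in 1:25) {
    hA <- list(e0 = 100, emax = runif(1, 0, 60), ec50 = 10^runif(1, -2, 1),
               slope = runif(1, 0.4, 4))
    hB <- list(e0 = 100, emax = runif(1, 0, 60), ec50 = 10^runif(1, -2, 1),
               slope = runif(1, 0.4, 4))
    d1 <- ascending_axis(5); d2 <- ascending_axis(5)
    expect_true(all(hsa_reference(hA, hB, d1, d2) >=
                      bliss_reference(hA, hB, d1, d2) - 1e-12))
  }
})

test_that("Loewe bisection matches the unit-slope closed form", {
  set.seed(7)
  worst <- 0
  for (rep in 1:100) {
    hA <- list(e0 = 100, emax = 0, ec50 = 10^runif(1, -2, 1), slope = 1)
    hB <- list(e0 = 100, emax = 0, ec50 = 10^runif(1, -2, 1), slope = 1)
    d1 <- c(0, sort(10^runif(5, -2, 1)))
    d2 <- c(0, sort(10^runif(5, -2, 1)))
    ref <- loewe_reference(hA, hB, d1, d2)
    closed <- outer(d1, d2, function(a, b)
      100 / (1 + a / hA$ec50 + b / hB$ec50))
    worst <- max(worst, max(abs(ref - closed)))
  }
  expect_lt(worst, 1e-6)
})

test_that("a drug combined with itself is exactly Loewe-additive (sham)", {
  h <- list(e0 = 100, emax = 5, ec50 = 0.4, slope = 1.7)
  d <- ascending_axis()
  obs <- outer(d, d, function(a, b) hill_viability(h, a + b))
  ref <- loewe_reference(h, h, d, d)
  sm <- synergy_map(dose_matrix(obs, d, d, 1, "L", 18), ref, "loewe")
  combo <- outer(d > 0, d > 0, `&`)
  expect_lt(max(abs(sm$delta[combo])), 1)
  # untreated corner sits on the e0 plane
  expect_equal(ref[1, 1], 100)
})

test_that("Loewe handles flat curves explicitly", {
  flat <- list(e0 = 100, emax = 100, ec50 = 1, slope = 1)
  act <- list(e0 = 100, emax = 0, ec50 = 0.5, slope = 1.2)
  d <- ascending_axis()
  # both flat: untreated plane, flagged
  ref2 <- loewe_reference(flat, flat, d, d)
  expect_true(all(ref2 == 100))
  expect_true(isTRUE(attr(ref2, "flagged")))
  # one flat: the active drug's curve governs the surface
  ref1 <- loewe_reference(flat, act, d, d)
  expect_equal(ref1[1, ], hill_viability(act, d), tolerance = 1e-6)
  expect_equal(ref1[4, ], hill_viability(act, d), tolerance = 1e-6)
})

test_that("synergy maps score reference minus observed over combination wells", {
  d <- ascending_axis()
  ref <- matrix(50, 6, 6)
  obs <- matrix(50, 6, 6)
  obs[3, 3] <- 30
  sm <- synergy_map(dose_matrix(obs, d, d, 1, "L", 18), ref, "bliss")
  expect_equal(sm$delta[3, 3], 20)
  expect_equal(sm$score, 20 / 25)
  expect_equal(sm$n_wells_used, 25)
  # observed == reference: all-zero map
  sm0 <- synergy_map(dose_matrix(ref, d, d, 1, "L", 18), ref, "hsa")
  expect_equal(sm0$score, 0)
  expect_true(all(sm0$delta == 0))
  # no combination wells -> undefined score
  one <- dose_matrix(matrix(100, 1, 1), 0, 0, 1, "L", 18)
  expect_error(synergy_map(one, matrix(100, 1, 1), "bliss"), "undefined")
})

test_that("compute_all_synergy applies replicate rules and emits per-method results", {
  hA <- list(e0 = 100, emax = 10, ec50 = 0.5, slope = 1.5)
  hB <- list(e0 = 100, emax = 30, ec50 = 0.2, slope = 1)
  mk <- function(rep, day = 18, noise = 0) {
    m <- bliss_true_matrix(hA, hB, pair_id = 1, cell_line = "L", day = day,
                           replicate = rep)
    m
  }
  res <- compute_all_synergy(list(mk(1), mk(2)))
  expect_length(res, 3)
  expect_setequal(vapply(res, `[[`, "", "method"), c("LOEWE", "BLISS", "HSA"))
  # Bliss-additive truth scores ~0 under the Bliss reference
  bl <- Filter(function(r) r$method == "BLISS", res)[[1]]
  expect_lt(abs(bl$score), 0.5)
  # both replicates monotherapy-broken: group absent, logged
  v <- mk(1)$values; v[2, 1] <- NA
  b1 <- dose_matrix(v, mk(1)$doses1, mk(1)$doses2, 1, "L", 18, 1)
  b2 <- dose_matrix(v, mk(1)$doses1, mk(1)$doses2, 1, "L", 18, 2)
  res2 <- compute_all_synergy(list(b1, b2), methods = "bliss")
  expect_length(res2, 0)
  expect_equal(nrow(attr(res2, "exclusions")), 1)
  # deterministic given input
  res3 <- compute_all_synergy(list(mk(1), mk(2)))
  expect_equal(synergy_results_table(res3), synergy_results_table(res))
})

test_that("the Bliss scorer is unbiased on exactly-additive matrices", {
  # matrices drawn from the Bliss product of true 4PL margins plus noise:
  # the fit-then-surface machinery must not manufacture synergy
  set.seed(77)
  d <- ascending_axis()
  scores <- vapply(1:30, function(i) {
    hA <- list(e0 = 100, emax = runif(1, 0, 30), ec50 = 10^runif(1, -1.2, 0.3),
               slope = runif(1, 0.8, 2.5))
    hB <- list(e0 = 100, emax = runif(1, 0, 30), ec50 = 10^runif(1, -1.2, 0.3),
               slope = runif(1, 0.8, 2.5))
    v <- pmax(outer(hill_viability(hA, d), hill_viability(hB, d)) / 100 +
                matrix(rnorm(36, 0, 5), 6), 0)
    m <- dose_matrix(v, d, d, 1, "L", 18)
    compute_all_synergy(list(m), methods = "bliss")[[1]]$score
  }, 0)
  sem <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 2 * sem)
})

test_that("simulated synergy sign is recovered from truth-level matrices", {
  d <- tiny_design(pair_ids = 1, n_replicates = 1)
  score_for <- function(alpha, seed) {
    tr <- simulate_trajectories(
      d, response = drug_response_params(synergy_alpha = alpha),
      noise_sd = 5, seed = seed, days = 18)
    tr$replicate <- 1
    mats <- matrices_from_table(tr, value_col = "viability_label",
                                provenance = "measured")
    res <- compute_all_synergy(mats, methods = "bliss")
    res[[1]]$score
  }
  seeds <- 1:20
  s_syn <- vapply(seeds, function(s) score_for(1, s), 0)
  s_null <- vapply(seeds, function(s) score_for(0, s + 500), 0)
  expect_gt(mean(s_syn), 0)
  expect_gt(mean(s_syn), mean(s_null))
  # the simulated monotherapy margins are not exactly 4PL (two exposure
  # windows, recovery, logistic growth), so the fitted-curve reference
  # carries a small model-mismatch offset; the null stays inside the
  # per-matrix noise band of ~1% viability
  expect_lt(abs(mean(s_null)), 1)
})
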