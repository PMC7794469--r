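test_that("replicate maps are consistent with the full-ensemble map", {
  p <- physical_params(confinement_radius_nm = 150)
  ens <- build_null_ensemble(growth_config(10, 40, master_seed = 2), p)
  # degenerate BLB: counts equal to the chain weights reproduce the
  # full-ensemble p_null exactly
  I <- chromogrow:::cpp_contact_indicators(ens$coords, 80)
  manual <- as.numeric(I %*% ens$weights) / sum(ens$weights)
  pn <- contact_probability(ens, 80)$p_null
  pairs <- chromogrow:::ut_pairs(10)
  expect_equal(manual, pn[pairs], tolerance = 1e-12)
})

test_that("BLB replicates are reproducible and average to the ensemble map", {
  p <- physical_params(confinement_radius_nm = 250)
  # near-uniform weights (frequent resampling) so that disjoint subsets
  # jointly tile the ensemble and the replicate mean is unbiased
  ens <- build_null_ensemble(growth_config(50, 2000, checkpoints = 1:50,
                                           resample_trigger = 0.95,
                                           master_seed = 3), p)
  cfg <- bootstrap_config(n_replicates = 5000, subset_size = 500,
                          n_subsets = 4, seed = 11)
  reps <- blb_replicates(ens, cfg)
  expect_equal(dim(reps), c(50 * 49 / 2, 5000))
  reps2 <- blb_replicates(ens, cfg)
  expect_identical(reps, reps2)
  # BLB consistency: replicate mean tracks the full-ensemble p_null
  pn <- contact_probability(ens)$p_null
  pairs <- chromogrow:::ut_pairs(50)
  expect_lt(max(abs(rowMeans(reps) - pn[pairs])), 0.01)
})

test_that("remainder replicates are distributed deterministically", {
  p <- physical_params(confinement_radius_nm = 150)
  ens <- build_null_ensemble(growth_config(8, 60, master_seed = 4), p)
  cfg <- bootstrap_config(n_replicates = 103, subset_size = 20,
                          n_subsets = 4, seed = 5)
  reps <- blb_replicates(ens, cfg)
  expect_equal(ncol(reps), 103)
})

test_that("quantile normalization maps ranks onto the pooled reference", {
  # hand-computed 4-pair example: reference is the mean sorted vector
  rep1 <- c(1, 3, 2, 4)
  obs <- c(10, 30, 40, 20)
  out <- quantile_normalize(matrix(rep1, 4), obs)
  # sorted columns: (1,2,3,4) and (10,20,30,40) -> reference (5.5,11,16.5,22)
  expect_equal(as.numeric(out$replicates), c(5.5, 16.5, 11, 22))
  expect_equal(out$p_obs, c(5.5, 16.5, 22, 11))

  # maps that are monotone transforms of each other become identical
  v <- c(0.3, 1.2, 0.7, 2.5, 0.1)
  out2 <- quantile_normalize(matrix(v, 5), v^3)
  expect_equal(as.numeric(out2$replicates), out2$p_obs)

  # normalizing a map against itself leaves it unchanged
  out3 <- quantile_normalize(matrix(v, 5), v)
  expect_equal(out3$p_obs, v)
  expect_equal(as.numeric(out3$replicates), v)

  # all-constant columns pass through unchanged
  out4 <- quantile_normalize(matrix(2, 5, 1), v)
  expect_equal(as.numeric(out4$replicates), rep(2, 5))
})

test_that("bootstrap p-values count exceedances with add-one smoothing", {
  M <- 500
  reps <- matrix(runif(3 * M), 3)
  obs <- c(2, -1, NA)
  # row 1: above every replicate; row 2: below every replicate
  expect_equal(pair_pvalues(reps[1:2, ], obs[1:2]),
               c(1 / (M + 1), 1))
  # exactly half the replicates at or above the observation
  reps3 <- matrix(c(rep(1, 250), rep(-1, 250)), 1)
  expect_equal(pair_pvalues(reps3, 0), 251 / 501)
})

test_that("BH adjustment is symmetric and respects the tested family", {
  p <- matrix(NA_real_, 4, 4)
  p[1, 3] <- 0.01; p[1, 4] <- 0.02; p[2, 4] <- 0.03
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q <- bh_adjust(p)
  expect_equal(q[1, 3], 0.03)  # 0.01 * 3 / 1
  expect_equal(q[3, 1], q[1, 3])
  expect_true(all(is.na(q[row(q) == col(q)])))
  expect_equal(q[upper.tri(q) & !is.na(q)],
               p.adjust(p[upper.tri(p) & !is.na(p)], "BH"))
  expect_true(all(q[!is.na(q)] >= p[!is.na(p)]))
})

test_that("implanted loops are called exactly against a quiet background", {
  # background propensities follow the null ensemble's own decay, with
  # three distant pairs boosted far above it
  p <- physical_params(confinement_radius_nm = 140)
  n <- 20
  ens <- build_null_ensemble(growth_config(n, 1500, master_seed = 6), p)
  pn <- contact_probability(ens)$p_null
  prop <- as_propensity(pn)
  loops <- rbind(c(2, 12), c(5, 17), c(7, 14), c(9, 19))
  prop$p_obs[loops] <- prop$p_obs[loops[, c(2, 1)]] <- 5 * max(prop$p_obs)
  cfg <- bootstrap_config(n_replicates = 5000, subset_size = 300,
                          n_subsets = 4, seed = 8)
  calls <- specific_interactions(prop, ens, cfg, alpha = 0.01)
  called <- which(calls$specific & upper.tri(calls$specific), arr.ind = TRUE)
  expect_equal(called[order(called[, 1]), , drop = FALSE],
               loops, ignore_attr = TRUE)
  # alpha = 1 calls every tested pair
  all_calls <- call_specific(calls$p_values, calls$q_values, alpha = 1,
                             propensity = prop, M = calls$M)
  expect_equal(all_calls$n_called, all_calls$n_tested)
  # q = 1 everywhere calls nothing
  q1 <- calls$q_values; q1[!is.na(q1)] <- 1
  none <- call_specific(calls$p_values, q1, 0.01, prop)
  expect_equal(none$n_called, 0)
  # calls are always a subset of nonzero observed pairs
  expect_true(all(prop$p_obs[calls$specific] > 0))
})

test_that("interaction types are tallied by unordered state pairs", {
  spec <- matrix(FALSE, 3, 3)
  spec[1, 2] <- spec[2, 1] <- spec[1, 3] <- spec[3, 1] <- TRUE
  calls <- structure(list(specific = spec), class = "specific_calls")
  t1 <- tally_types(calls, c("A", "A", "I"))
  expect_equal(unname(t1[c("A-A", "A-I")]), c(0.5, 0.5))
  expect_equal(sum(t1), 1)
  t2 <- tally_types(calls, c("P", "P", "P"))
  expect_equal(unname(t2["P-P"]), 1)
  t3 <- tally_types(calls, c("A", NA, "I"))
  expect_equal(unname(t3["any-U"]), 0.5)
})
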