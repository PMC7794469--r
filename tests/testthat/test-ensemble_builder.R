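make_calls <- function(prop, specific_pairs) {
  n <- nrow(prop$p_obs)
  spec <- matrix(FALSE, n, n)
  if (nrow(specific_pairs)) {
    spec[specific_pairs] <- TRUE
    spec[specific_pairs[, c(2, 1), drop = FALSE]] <- TRUE
  }
  structure(list(specific = spec), class = "specific_calls")
}

test_that("target selection matches the requested mode", {
  set.seed(2)
  n <- 15
  p <- matrix(runif(n * n), n)
  p <- (p + t(p)) / 2
  p[1, 4] <- p[4, 1] <- 0                    # one zero pair
  prop <- as_propensity(p)
  calls <- make_calls(prop, rbind(c(2, 8), c(3, 12)))

  t_spec <- select_targets(prop, calls, "specific")
  expect_equal(t_spec$n_targets, 2)
  expect_equal(t_spec$q[2, 8], min(prop$p_obs[2, 8], 1))

  empty <- select_targets(prop, make_calls(prop, matrix(0, 0, 2)), "specific")
  expect_equal(empty$n_targets, 0)
  expect_true(all(empty$q == 0))

  t_all <- select_targets(prop, mode = "all")
  eligible <- sum(prop$p_obs[chromogrow:::ut_pairs(n)] > 0 &
                    (chromogrow:::ut_pairs(n)[, 2] -
                       chromogrow:::ut_pairs(n)[, 1]) >= 2)
  expect_equal(t_all$n_targets, eligible)

  t_ns1 <- select_targets(prop, calls, "nonspecific", seed = 9)
  t_ns2 <- select_targets(prop, calls, "nonspecific", seed = 9)
  expect_identical(t_ns1$q, t_ns2$q)
  expect_equal(t_ns1$n_targets, 2)
  expect_true(all(t_ns1$q[calls$specific] == 0))
})

test_that("empty targets reduce exactly to the null model", {
  p <- physical_params(confinement_radius_nm = 200)
  cfg <- growth_config(25, 200, master_seed = 12)
  nul <- build_null_ensemble(cfg, p)
  tgt <- select_targets(as_propensity(matrix(1, 25, 25)),
                        make_calls(as_propensity(matrix(1, 25, 25)),
                                   matrix(0, 0, 2)),
                        "specific")
  expect_equal(tgt$n_targets, 0)
  con <- grow_constrained_ensemble(tgt, p, cfg)
  expect_identical(nul$coords, con$coords)
  expect_identical(nul$weights, con$weights)
  expect_equal(con$kind, "constrained")
})

test_that("a strong single target is realized after calibration", {
  p <- physical_params(confinement_radius_nm = 200)
  n <- 30
  q <- matrix(0, n, n); q[1, n] <- q[n, 1] <- 1
  tgt <- structure(list(q = q, binning = NULL, mode = "custom",
                        n_targets = 1L), class = "target_map")
  cal <- calibrate(tgt, p, growth_config(n, 500, master_seed = 3),
                   rounds = 4, batch = 500)
  ens <- grow_constrained_ensemble(tgt, p,
                                   growth_config(n, 1500, master_seed = 11),
                                   cal)
  psim <- simulate_contact_map(ens)
  nul <- simulate_contact_map(
    build_null_ensemble(growth_config(n, 1500, master_seed = 12), p))
  expect_gte(psim[1, n], 0.8)
  expect_lt(nul[1, n], 0.2)
  expect_true(all(validate_ensemble(ens)))
  # determinism
  ens2 <- grow_constrained_ensemble(tgt, p,
                                    growth_config(n, 1500, master_seed = 11),
                                    cal)
  expect_identical(ens$coords, ens2$coords)
})

test_that("calibration against the null's own map stays near unit bias", {
  p <- physical_params(confinement_radius_nm = 220)
  n <- 30
  nul <- build_null_ensemble(growth_config(n, 2000, master_seed = 5), p)
  pn <- simulate_contact_map(nul)
  q <- pn
  q[abs(row(q) - col(q)) < 2] <- 0  # target only non-adjacent pairs
  tgt <- structure(list(q = q, binning = NULL, mode = "custom",
                        n_targets = sum(q[upper.tri(q)] > 0)),
                   class = "target_map")
  cal <- calibrate(tgt, p, growth_config(n, 1000, master_seed = 6),
                   rounds = 3, batch = 1000)
  sup <- tgt$q > 0
  expect_true(all(cal$bias[sup] >= 0.8 & cal$bias[sup] <= 1.25))
  # reported history is non-decreasing by best-state selection
  expect_true(all(diff(cal$history) >= 0))
})

test_that("map correlation separates shared decay from stratum signal", {
  set.seed(4)
  n <- 50
  noise_a <- matrix(rnorm(n * n), n); noise_a <- (noise_a + t(noise_a)) / 2
  noise_b <- matrix(rnorm(n * n), n); noise_b <- (noise_b + t(noise_b)) / 2
  expect_equal(map_correlation(noise_a, noise_a), 1)
  expect_equal(map_correlation(noise_a, noise_a, "distance_adjusted"), 1)
  # independent maps: negligible correlation
  expect_lt(abs(map_correlation(noise_a, noise_b)), 0.1)
  # adding the same strong distance decay to both inflates r but not r'
  decay <- 10 / (abs(row(noise_a) - col(noise_a)) + 1)
  a <- noise_a * 0.3 + decay
  b <- noise_b * 0.3 + decay
  expect_gt(map_correlation(a, b), 0.5)
  expect_lt(abs(map_correlation(a, b, "distance_adjusted")), 0.15)
  # constant map: undefined, flagged
  expect_warning(r <- map_correlation(matrix(1, n, n), noise_a), "constant")
  expect_true(is.na(r))
})

test_that("pairwise multibody fractions equal the simulated contact map", {
  p <- physical_params(confinement_radius_nm = 180)
  ens <- build_null_ensemble(growth_config(20, 300, master_seed = 7), p)
  psim <- simulate_contact_map(ens)
  mb <- multibody_fraction(ens, list(3, 15))
  expect_equal(mb$fraction, psim[3, 15], tolerance = 1e-12)
})
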