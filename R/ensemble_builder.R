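#' Select modeling targets from propensities and calls
#'
#' Builds the target contact-probability map `q_target = min(p_obs, 1)` on
#' the selected pairs and 0 elsewhere. Modes: `"specific"` uses only the
#' called pairs; `"all"` every tested nonzero pair; `"nonspecific"` a
#' random sample of non-called nonzero pairs of the same cardinality as
#' the specific set (with a warning if fewer are available). Propensities
#' are clipped at 1 because the model equates a target with the proportion
#' of chains in contact, which is bounded by 1.
#'
#' @param p_obs A `propensity_map`.
#' @param calls A `specific_calls` object (required for `"specific"` and
#'   `"nonspecific"`).
#' @param mode `"specific"`, `"all"`, or `"nonspecific"`.
#' @param seed Seed for the nonspecific sample.
#' @return An object of class `target_map` with matrix `q`.
#' @export
select_targets <- function(p_obs, calls = NULL,
                           mode = c("specific", "all", "nonspecific"),
                           seed = 1L) {
  mode <- match.arg(mode)
  P <- p_obs$p_obs
  n <- nrow(P)
  pairs <- ut_pairs(n)
  eligible <- (pairs[, 2] - pairs[, 1]) >= 2 &
    !is.na(P[pairs]) & P[pairs] > 0
  sel <- switch(mode,
    all = eligible,
    specific = {
      stopifnot(!is.null(calls))
      calls$specific[pairs]
    },
    nonspecific = {
      stopifnot(!is.null(calls))
      pool <- which(eligible & !calls$specific[pairs])
      want <- sum(calls$specific[pairs])
      if (length(pool) < want) {
        warning("fewer non-called nonzero pairs than specific calls; ",
                "using all available")
        want <- length(pool)
      }
      set.seed(seed)
      out <- rep(FALSE, nrow(pairs))
      out[sample(pool, want)] <- TRUE
      out
    })
  q <- matrix(0, n, n)
  q[pairs[sel, , drop = FALSE]] <- pmin(P[pairs][sel], 1)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(q = q, binning = p_obs$binning, mode = mode,
                 n_targets = sum(sel)),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> mode '%s', %d target pairs over %d bins\n",
              x$mode, x$n_targets, nrow(x$q)))
  invisible(x)
}

#' Create a calibration state
#'
#' Multiplicative per-pair bias factors applied to the target
#' probabilities during constrained growth, initialized at 1.
#'
#' @param n Number of beads.
#' @return An object of class `calibration_state`.
#' @export
calibration_state <- function(n) {
  structure(list(bias = matrix(1, n, n), round = 0L,
                 history = numeric(0)),
            class = "calibration_state")
}

effective_targets <- function(target, calib = NULL, cap = 0.995) {
  q <- target$q
  if (!is.null(calib)) q <- q * calib$bias
  q[q > 0] <- pmin(q[q > 0], cap)
  q
}

#' Grow a Hi-C-concordant constrained ensemble
#'
#' Identical growth mechanics to [build_null_ensemble()], with one change:
#' each valid trial position for bead `t` is additionally weighted by the
#' product, over earlier beads `j` with a target on `(j, t)`, of the
#' per-pair Bernoulli factor `b*q` if the trial is within the ligation
#' threshold of bead `j` and `1 - min(1, b*q)` otherwise (`b` the
#' calibration bias, effective probabilities capped at 0.995 so no single
#' pair becomes a hard constraint). The trial is chosen with probability
#' proportional to this weight and the chain's importance weight tracks
#' the proposal/target ratio, so the weighted ensemble targets the
#' geometric prior tilted by the Bernoulli likelihood of the targets. An
#' empty target map reduces exactly to the null model (identical chains
#' for identical seeds).
#'
#' @param target A `target_map`.
#' @param params A [physical_params()].
#' @param config A [growth_config()]; `config$n_beads` must equal the
#'   number of bins of the target.
#' @param calib Optional [calibration_state()] from [calibrate()].
#' @return A `chain_ensemble` of kind `"constrained"`.
#' @export
grow_constrained_ensemble <- function(target, params, config, calib = NULL) {
  stopifnot(nrow(target$q) == config$n_beads)
  qeff <- effective_targets(target, calib)
  set.seed(config$master_seed)
  raw <- grow_raw(config, params, qeff = qeff)
  raw_to_ensemble(raw, config, params, "constrained",
                  extra = list(target_mode = target$mode))
}

#' Calibrate the constrained grower against its targets
#'
#' Iterative proportional-fitting loop: grow a batch, aggregate its
#' contact map, then multiply each target pair's bias by
#' `clip((q_target / p_sim)^damp, 1/kappa, kappa)` (a vanished pair gets
#' the maximal boost `kappa`), so that over rounds the aggregated contact
#' frequencies converge onto the targets. The square-root damping
#' (`damp = 0.5`) and the modest clip (`kappa = 2`) keep the multiplicative
#' updates from oscillating: because every target pair tilts every later
#' growth step, undamped full-ratio updates overshoot collectively. Stops
#' early once the Pearson correlation to the target (on target pairs)
#' stops improving by more than `plateau_tol`; the best state seen is
#' returned, so the reported history is non-decreasing.
#'
#' @param target A `target_map`.
#' @param params A [physical_params()].
#' @param config A [growth_config()]; its `n_chains` is overridden by
#'   `batch` during calibration.
#' @param rounds Maximum calibration rounds (>= 1).
#' @param batch Chains per calibration round.
#' @param kappa Per-round clip factor on bias updates (default 2).
#' @param damp Exponent damping the per-round ratio updates (default 0.5).
#' @param bias_max Clamp on the cumulative per-pair bias (default 4): the
#'   collective response of the grower to many simultaneous tilts is
#'   sublinear, so unbounded ratio accumulation on hard-to-satisfy pairs
#'   destabilizes later rounds.
#' @param plateau_tol Early-stop improvement threshold (default 1e-3).
#' @return A `calibration_state` with the best `bias`, the running-best
#'   correlation `history`, and `round` the round it was found.
#' @export
calibrate <- function(target, params, config, rounds = 10, batch = 1000,
                      kappa = 2, damp = 0.5, bias_max = 4,
                      plateau_tol = 1e-3) {
  stopifnot(rounds >= 1)
  n <- config$n_beads
  sup <- target$q > 0 & upper.tri(target$q)
  state <- calibration_state(n)
  best <- state
  best_r <- -Inf
  raw_hist <- numeric(0)
  cfg <- config
  cfg$n_chains <- as.integer(batch)
  for (rd in seq_len(rounds)) {
    cfg$master_seed <- config$master_seed + rd
    ens <- grow_constrained_ensemble(target, params, cfg, state)
    psim <- simulate_contact_map(ens)
    r <- suppressWarnings(cor(psim[sup], target$q[sup]))
    if (is.na(r)) r <- 0
    raw_hist <- c(raw_hist, r)
    if (r > best_r) {
      best_r <- r
      best <- state
      best$round <- rd
    }
    improved <- rd == 1 || r > max(raw_hist[-rd]) + plateau_tol
    # update for the next round
    ratio <- matrix(1, n, n)
    ratio[sup] <- ifelse(psim[sup] <= 0, kappa,
                         pmin(pmax((target$q[sup] / psim[sup])^damp,
                                   1 / kappa), kappa))
    ratio[lower.tri(ratio)] <- t(ratio)[lower.tri(ratio)]
    state$bias <- pmin(pmax(state$bias * ratio, 1 / bias_max), bias_max)
    state$round <- rd
    state$history <- cummax(raw_hist)
    if (!improved && rd > 1) break
  }
  best$history <- cummax(raw_hist)
  attr(best, "raw_history") <- raw_hist
  best
}

#' Aggregate an ensemble into a simulated contact map
#'
#' The weighted contact frequency of every bin pair at threshold `d_c`,
#' i.e. the simulated Hi-C map of the ensemble.
#'
#' @param ensemble A `chain_ensemble`.
#' @param d_c Ligation threshold (nm).
#' @return A symmetric numeric matrix of contact probabilities.
#' @export
simulate_contact_map <- function(ensemble,
                                 d_c = ensemble$params$ligation_threshold_nm) {
  stopifnot(d_c > 0, ensemble$n_chains >= 1)
  cpp_contact_map(ensemble$coords, ensemble$weights, d_c)
}

#' Correlation between two contact maps
#'
#' `"pearson"`: Pearson r over all valid pairs with `i < j` (diagonal
#' excluded). `"distance_adjusted"`: the stratum-adjusted correlation
#' (SCC): a Pearson correlation per genomic-distance stratum `|i - j|`,
#' combined with weights proportional to stratum size times the product of
#' the two stratum standard deviations, which removes the inflation that
#' the shared distance decay lends to the plain r.
#'
#' @param map_a,map_b Symmetric numeric matrices of equal dimension.
#' @param mode `"pearson"` or `"distance_adjusted"`.
#' @param mask Optional logical matrix restricting the comparison (only
#'   upper-triangle entries are used).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   map is constant over the compared pairs.
#' @export
map_correlation <- function(map_a, map_b,
                            mode = c("pearson", "distance_adjusted"),
                            mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(dim(map_a) == dim(map_b)))
  n <- nrow(map_a)
  valid <- upper.tri(map_a) & is.finite(map_a) & is.finite(map_b)
  if (!is.null(mask)) valid <- valid & mask
  a <- map_a[valid]; b <- map_b[valid]
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) {
    warning("constant map; correlation undefined")
    return(NA_real_)
  }
  if (mode == "pearson") return(cor(a, b))
  d <- (col(map_a) - row(map_a))[valid]
  num <- 0; den <- 0
  for (s in unique(d)) {
    i <- d == s
    if (sum(i) < 3) next
    sa <- sd(a[i]); sb <- sd(b[i])
    if (sa == 0 || sb == 0) next
    w <- sum(i) * sa * sb
    num <- num + w * cor(a[i], b[i])
    den <- den + w
  }
  if (den == 0) {
    warning("no usable strata; correlation undefined")
    return(NA_real_)
  }
  num / den
}
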