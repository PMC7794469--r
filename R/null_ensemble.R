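#' Growth configuration for sequential chain sampling
#'
#' Controls the sequential-importance-sampling chain grower: at each step a
#' bead is appended at one of `n_trial_directions` uniformly sampled
#' directions on the bond sphere, chosen among the collision-free,
#' in-confinement trials; the Rosenbluth factor (valid trials / K) per step
#' accumulates into the chain's importance weight, so the weighted ensemble
#' targets the uniform distribution over all geometrically realizable
#' self-avoiding confined chains. At each checkpoint length, if the
#' effective sample size `(sum w)^2 / sum w^2` of the population falls
#' below `resample_trigger * n_chains`, chains are resampled systematically
#' in proportion to their weights and weights are reset (total preserved).
#'
#' @param n_beads Beads per chain.
#' @param n_chains Number of chains grown in parallel.
#' @param n_trial_directions Trial directions K per growth step.
#' @param checkpoints Strictly increasing chain lengths at which resampling
#'   is considered; default every `ceiling(n_beads / 20)` beads.
#' @param resample_trigger ESS fraction below which resampling fires
#'   (0 disables resampling).
#' @param master_seed Integer seed; ensembles are bit-reproducible given it.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(n_beads, n_chains,
                          n_trial_directions = 32,
                          checkpoints = NULL,
                          resample_trigger = 0.5,
                          master_seed = 1L) {
  stopifnot(n_beads >= 1, n_chains >= 1, n_trial_directions >= 1,
            resample_trigger >= 0, resample_trigger <= 1)
  if (is.null(checkpoints)) {
    step <- ceiling(n_beads / 20)
    checkpoints <- seq(step, n_beads, by = step)
  }
  checkpoints <- as.integer(checkpoints)
  stopifnot(all(diff(checkpoints) > 0), all(checkpoints <= n_beads),
            all(checkpoints >= 1))
  structure(list(n_beads = as.integer(n_beads),
                 n_chains = as.integer(n_chains),
                 n_trial_directions = as.integer(n_trial_directions),
                 checkpoints = checkpoints,
                 resample_trigger = resample_trigger,
                 master_seed = as.integer(master_seed)),
            class = "growth_config")
}

no_targets <- matrix(numeric(0), 0, 0)

grow_raw <- function(config, params, qeff = NULL, anchors = NULL) {
  if (is.null(qeff)) qeff <- no_targets
  if (is.null(anchors)) {
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
  } else {
    centers <- anchors$centers
    radii <- anchors$radii
    stopifnot(nrow(centers) == config$n_beads,
              length(radii) == config$n_beads)
  }
  cpp_grow_ensemble(config$n_beads, config$n_chains,
                    config$n_trial_directions,
                    params$bead_diameter_nm,
                    params$ligation_threshold_nm,
                    params$confinement_radius_nm,
                    config$checkpoints,
                    config$resample_trigger,
                    qeff, centers, radii)
}

raw_to_ensemble <- function(raw, config, params, kind, extra = list()) {
  alive <- raw$alive
  if (!any(alive))
    stop("all chains died during growth; confinement too tight for the ",
         "requested chain length")
  coords <- raw$coords[, , alive, drop = FALSE]
  lw <- raw$logw[alive]
  w <- exp(lw - max(lw))
  prov <- c(list(config = config, master_seed = config$master_seed,
                 n_resamples = raw$n_resamples, n_deaths = raw$n_deaths,
                 n_grown = config$n_chains), extra)
  new_chain_ensemble(coords, w, params, kind, prov)
}

#' Grow a single self-avoiding confined chain
#'
#' Sequential placement: the first bead uniform in the confinement sphere,
#' each further bead at one of K uniformly sampled directions on the bond
#' sphere, chosen uniformly among the collision-free, in-confinement
#' trials. The returned weight is the chain's Rosenbluth factor, the
#' product over steps of (valid trials / K).
#'
#' @param config A [growth_config()] (its `n_chains` is ignored).
#' @param params A [physical_params()].
#' @param seed Integer seed for this chain.
#' @return A `conformation`, or `NULL` (with a warning) if the chain died:
#'   at some step all K trials collided or left the confinement. Attrition
#'   is handled at ensemble level by checkpoint resampling.
#' @export
grow_chain <- function(config, params, seed = config$master_seed) {
  stopifnot(params$confinement_radius_nm >= params$bead_diameter_nm)
  cfg <- config
  cfg$n_chains <- 1L
  cfg$resample_trigger <- 0
  set.seed(seed)
  raw <- grow_raw(cfg, params)
  if (!raw$alive[1]) {
    warning("chain died during growth")
    return(NULL)
  }
  new_conformation(matrix(raw$coords[, , 1], ncol = 3), exp(raw$logw[1]),
                   rng_seed = seed)
}

#' Build the confined random-polymer null ensemble
#'
#' Grows `n_chains` chains in parallel with checkpoint resampling (see
#' [growth_config()]). The result is the physical null model: a weighted
#' ensemble of random, self-avoiding chromatin chains in spherical
#' confinement, from which random-collision contact probabilities are
#' estimated. Fully reproducible from `config$master_seed`.
#'
#' @param config A [growth_config()].
#' @param params A [physical_params()].
#' @return A `chain_ensemble` of kind `"null"`.
#' @export
build_null_ensemble <- function(config, params) {
  set.seed(config$master_seed)
  raw <- grow_raw(config, params)
  raw_to_ensemble(raw, config, params, "null")
}

#' Random-collision contact probability map
#'
#' Weighted contact frequencies of the ensemble:
#' `p(i, j) = sum_k I_k(i, j) w_k / sum_k w_k`, with `I_k = 1` iff beads
#' `i` and `j` of chain `k` are closer than `d_c`. Adjacent beads are
#' always in contact because the bond length (one bead diameter) is below
#' the ligation threshold.
#'
#' @param ensemble A `chain_ensemble`.
#' @param d_c Ligation threshold in nm; defaults to the ensemble's
#'   parameters.
#' @return An object of class `null_contact_map`: `p_null` matrix,
#'   `n_effective` (ESS of the weights), `params`.
#' @export
contact_probability <- function(ensemble,
                                d_c = ensemble$params$ligation_threshold_nm) {
  if (d_c <= 0) stop("d_c must be positive")
  stopifnot(ensemble$n_chains >= 1)
  p <- cpp_contact_map(ensemble$coords, ensemble$weights, d_c)
  w <- ensemble$weights / sum(ensemble$weights)
  structure(list(p_null = p, n_effective = 1 / sum(w^2),
                 params = ensemble$params),
            class = "null_contact_map")
}

#' @export
print.null_contact_map <- function(x, ...) {
  cat(sprintf("<null_contact_map> %d bins, effective sample size %.0f\n",
              nrow(x$p_null), x$n_effective))
  invisible(x)
}
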