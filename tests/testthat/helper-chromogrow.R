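# Shared fixtures and independent oracles for the test suite.

# Wrap a bare symmetric matrix as a propensity map (propensity of a contact
# map: normalize by the mean first-off-diagonal value).
as_propensity <- function(p, binning = NULL) {
  n <- nrow(p)
  if (is.null(binning)) binning <- genomic_binning("chrT", 0, 2000, n)
  e1 <- mean(p[cbind(seq_len(n - 1), seq_len(n - 1) + 1)])
  structure(list(p_obs = p / e1, e_diag1 = e1, mask = rep(FALSE, n),
                 binning = binning),
            class = "propensity_map")
}

# Bare chain ensemble from a list of coordinate matrices (analysis-level
# fixtures; not necessarily physically valid chains).
as_ensemble <- function(coord_list, weights = rep(1, length(coord_list)),
                        params = physical_params(confinement_radius_nm = 1e6)) {
  n <- nrow(coord_list[[1]])
  coords <- array(0, c(n, 3, length(coord_list)))
  for (k in seq_along(coord_list)) coords[, , k] <- coord_list[[k]]
  chromogrow:::new_chain_ensemble(coords, weights, params, "fixture",
                                  list(master_seed = NA))
}

# Naive rejection-sampling oracle: free chains (uniform start in the sphere,
# uniform bond directions), accepted only if fully inside the confinement
# and self-avoiding. Independent of the sequential grower.
reject_sample_chains <- function(n_chains, n_beads, radius, bond = 25) {
  out <- array(NA_real_, c(n_beads, 3, n_chains))
  got <- 0
  while (got < n_chains) {
    B <- 20000
    u <- matrix(runif(B * (n_beads - 1)), B)
    v <- matrix(runif(B * (n_beads - 1)), B)
    z <- 2 * u - 1
    rho <- sqrt(pmax(0, 1 - z^2))
    phi <- 2 * pi * v
    dx <- bond * rho * cos(phi); dy <- bond * rho * sin(phi); dz <- bond * z
    d0 <- matrix(rnorm(3 * B), B)
    d0 <- d0 / sqrt(rowSums(d0^2))
    r0 <- radius * runif(B)^(1 / 3)
    x <- cbind(r0 * d0[, 1], t(apply(dx, 1, cumsum)) + r0 * d0[, 1])
    y <- cbind(r0 * d0[, 2], t(apply(dy, 1, cumsum)) + r0 * d0[, 2])
    z3 <- cbind(r0 * d0[, 3], t(apply(dz, 1, cumsum)) + r0 * d0[, 3])
    ok <- rowSums(x^2 + y^2 + z3^2 > radius^2) == 0
    for (i in 1:(n_beads - 2)) {
      for (j in (i + 2):n_beads) {
        if (!any(ok)) break
        d2 <- (x[, i] - x[, j])^2 + (y[, i] - y[, j])^2 + (z3[, i] - z3[, j])^2
        ok <- ok & d2 >= bond^2
      }
    }
    idx <- which(ok)
    take <- idx[seq_len(min(length(idx), n_chains - got))]
    for (k in take) {
      got <- got + 1
      out[, , got] <- cbind(x[k, ], y[k, ], z3[k, ])
    }
  }
  out
}

# Weighted two-sample Kolmogorov-Smirnov statistic.
weighted_ks <- function(x, wx, y, wy = rep(1, length(y))) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) sum(wx[x <= g]) / sum(wx), numeric(1))
  Fy <- vapply(grid, function(g) sum(wy[y <= g]) / sum(wy), numeric(1))
  max(abs(Fx - Fy))
}

# Tight two-cluster conformation with the second cluster starting at bead
# `junction`; clusters sit `sep` nm apart with `spread` nm of jitter.
two_cluster_coords <- function(n_beads, junction, sep = 400, spread = 3) {
  ctr <- rbind(c(-sep / 2, 0, 0), c(sep / 2, 0, 0))
  grp <- c(rep(1, junction - 1), rep(2, n_beads - junction + 1))
  ctr[grp, ] + matrix(runif(3 * n_beads, -spread, spread), n_beads)
}
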