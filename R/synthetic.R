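#' Generate a synthetic Hi-C contact matrix with known ground truth
#'
#' Emulates the statistical structure the pipeline consumes: a power-law
#' distance decay, multiplicative TAD blocks, implanted loop pairs, and
#' overdispersed (negative binomial) count noise. Expected counts are
#' `mu_ij = base_count * |i-j|^decay_exponent`, multiplied by the
#' enrichment of every TAD covering both bins and by the loop enrichment
#' at loop pairs. With `noise_dispersion > 0` counts are drawn
#' `NB(mu, size = 1/dispersion)`; with 0 the expected counts are returned
#' noise-free.
#'
#' @param n_bins Number of bins (>= 20).
#' @param decay_exponent Power-law exponent of the distance decay
#'   (default -1).
#' @param decay_profile Optional numeric vector of relative contact
#'   frequencies per genomic distance (`decay_profile[s]` for `|i-j| = s`,
#'   normalized internally so distance 1 equals 1); overrides the power
#'   law. Passing the measured decay of a polymer null ensemble makes the
#'   background physically realizable by a chain ensemble, with the TAD
#'   blocks and loops the only deviations from polymer behavior.
#' @param tads List of `c(start, end, enrichment)` triples (1-based bins,
#'   inclusive), non-nested.
#' @param loops List of `c(i, j, enrichment)` triples, enrichment > 1.
#' @param noise_dispersion Negative-binomial dispersion (default 0.1;
#'   0 = deterministic).
#' @param seed Integer seed; output is deterministic given seed and spec.
#' @param base_count Expected count at distance 1 bin.
#' @param binning Optional [genomic_binning()]; default chrS at 2 kb.
#' @return List with `matrix` (a `contact_matrix`), `mu` (expected
#'   counts), and `labels`: `loop_pairs` (matrix of i, j rows) and
#'   `tad_pairs` (logical matrix of within-TAD pairs).
#' @export
generate_toy_hic <- function(n_bins, decay_exponent = -1, tads = list(),
                             loops = list(), noise_dispersion = 0.1,
                             seed = 1L, base_count = 100,
                             decay_profile = NULL, binning = NULL) {
  stopifnot(n_bins >= 20, noise_dispersion >= 0)
  if (is.null(binning))
    binning <- genomic_binning("chrS", 0, 2000, n_bins)
  d <- abs(row(diag(n_bins)) - col(diag(n_bins)))
  if (is.null(decay_profile)) {
    mu <- base_count * ifelse(d == 0, 0, d^decay_exponent)
  } else {
    stopifnot(length(decay_profile) >= n_bins - 1, all(decay_profile > 0))
    prof <- decay_profile / decay_profile[1]
    mu <- base_count * ifelse(d == 0, 0, prof[pmax(d, 1)])
  }
  tad_pairs <- matrix(FALSE, n_bins, n_bins)
  for (t in tads) {
    stopifnot(length(t) == 3, t[1] >= 1, t[2] <= n_bins, t[1] < t[2])
    r <- t[1]:t[2]
    mu[r, r] <- mu[r, r] * t[3]
    tad_pairs[r, r] <- TRUE
  }
  loop_pairs <- matrix(integer(0), 0, 2)
  for (l in loops) {
    stopifnot(length(l) == 3, l[3] > 1)
    i <- min(l[1], l[2]); j <- max(l[1], l[2])
    mu[i, j] <- mu[i, j] * l[3]
    mu[j, i] <- mu[i, j]
    loop_pairs <- rbind(loop_pairs, c(i, j))
  }
  diag(mu) <- 0
  if (noise_dispersion > 0) {
    set.seed(seed)
    up <- upper.tri(mu)
    counts <- matrix(0, n_bins, n_bins)
    counts[up] <- rnbinom(sum(up), mu = mu[up], size = 1 / noise_dispersion)
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  } else {
    counts <- mu
  }
  list(matrix = new_contact_matrix(counts, binning),
       mu = mu,
       labels = list(loop_pairs = loop_pairs, tad_pairs = tad_pairs))
}

packing_radius <- function(n_beads, packing, bead_diameter = 25) {
  # sphere radius at which n_beads beads occupy `packing` volume fraction
  (bead_diameter / 2) * (n_beads / packing)^(1 / 3)
}

fixture_params <- function(radius, resolution_bp = 2000) {
  physical_params(resolution_bp = resolution_bp,
                  confinement_radius_nm = radius)
}

#' Generate labeled synthetic conformations
#'
#' Fixture ensembles with known structural ground truth, all grown with
#' the package's own sequential sampler so every chain satisfies the bond,
#' excluded-volume, and confinement invariants:
#'
#' * `"globule-pair"`: each chain is two compact globules (per-bead
#'   spherical scaffolds at 25 percent packing) whose surfaces are 60 nm
#'   apart, joined by a short 4-bead linker guided across the gap — the
#'   central linker bead is the planted single-cell domain boundary. A
#'   window of about `n_beads / 5` bins suits boundary calling on these
#'   chains.
#' * `"coil"`: unstructured chains at 1 percent packing density, the reference
#'   density of a multi-megabase region in a fly nucleus.
#' * `"mixture"`: half compact chains (30 percent packing) and half
#'   extended chains (2 percent packing), with generating labels, for
#'   clustering tests.
#'
#' @param kind `"globule-pair"`, `"coil"`, or `"mixture"`.
#' @param n Number of conformations.
#' @param n_beads Beads per chain (default 64).
#' @param seed Integer seed.
#' @return List with `ensemble` (a `chain_ensemble`), `labels` (mixture:
#'   `"compact"`/`"extended"` per chain), and `junction` (globule-pair:
#'   the planted boundary position at the middle of the linker).
#' @export
generate_labeled_conformations <- function(kind = c("globule-pair", "coil",
                                                    "mixture"),
                                           n, n_beads = 64, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "coil") {
    params <- fixture_params(packing_radius(n_beads, 0.01))
    cfg <- growth_config(n_beads, n, master_seed = seed)
    return(list(ensemble = build_null_ensemble(cfg, params),
                labels = NULL, junction = NULL))
  }
  if (kind == "mixture") {
    n1 <- floor(n / 2); n2 <- n - n1
    pc <- fixture_params(packing_radius(n_beads, 0.30))
    pe <- fixture_params(packing_radius(n_beads, 0.02))
    # oversample: growth at 30 percent packing loses some chains, and the
    # fixture must deliver exactly the requested class sizes
    take <- function(params, want, sd) {
      e <- build_null_ensemble(
        growth_config(n_beads, max(50, 3 * want), master_seed = sd), params)
      if (e$n_chains < want) stop("mixture fixture: too few chains survived")
      e$coords[, , seq_len(want), drop = FALSE]
    }
    c1 <- take(pc, n1, seed)
    c2 <- take(pe, n2, seed + 1)
    coords <- array(0, c(n_beads, 3, n))
    coords[, , seq_len(n1)] <- c1
    coords[, , n1 + seq_len(n2)] <- c2
    ens <- new_chain_ensemble(coords, rep(1, n), pe, "fixture",
                              list(master_seed = seed, kind = "mixture"))
    return(list(ensemble = ens,
                labels = rep(c("compact", "extended"), c(n1, n2)),
                junction = NULL))
  }
  # globule-pair: globule 1 | 4-bead linker | globule 2
  stopifnot(n_beads >= 24)
  n_tube <- 4L
  m <- (n_beads - n_tube) %/% 2
  m2 <- n_beads - n_tube - m
  r <- packing_radius(max(m, m2), 0.25)
  gap <- 60
  half <- r + gap / 2
  centers <- matrix(0, n_beads, 3)
  centers[seq_len(m), 1] <- -half
  centers[(m + n_tube + 1):n_beads, 1] <- half
  centers[m + seq_len(n_tube), 1] <- seq(-gap / 2 - 5, gap / 2 + 5,
                                         length.out = n_tube)
  radii <- rep(r, n_beads)
  radii[m + seq_len(n_tube)] <- 20
  params <- fixture_params(2 * (2 * r + gap))
  # checkpoints every 3 beads plus a dense band around the junction, where
  # most attrition happens
  cps <- sort(unique(c(seq(3, n_beads, by = 3), (m - 1):(m + n_tube + 3))))
  # Each fixture conformation comes from its own small population, so the
  # n conformations are mutually independent: checkpoint resampling within
  # one population would otherwise collapse all chains onto few ancestors.
  # Crossing the junction gap is where chains die; the dense checkpoint
  # band there lets survivors repopulate a batch. Deterministic given seed.
  coords <- array(NA_real_, c(n_beads, 3, n))
  weights <- numeric(n)
  for (i in seq_len(n)) {
    done <- FALSE
    for (attempt in 0:9) {
      cfg <- growth_config(n_beads, 100, checkpoints = cps,
                           resample_trigger = 0.5,
                           master_seed = seed + 101L * i + 100000L * attempt)
      set.seed(cfg$master_seed)
      raw <- grow_raw(cfg, params, anchors = list(centers = centers,
                                                  radii = radii))
      if (raw$n_alive > 0) {
        pick <- which(raw$alive)[1]
        coords[, , i] <- raw$coords[, , pick]
        weights[i] <- 1
        done <- TRUE
        break
      }
    }
    if (!done) stop("globule-pair fixture: chain population died repeatedly")
  }
  ens <- new_chain_ensemble(coords, weights, params, "fixture",
                            list(master_seed = seed, kind = "globule-pair"))
  list(ensemble = ens, labels = NULL, junction = m + n_tube %/% 2 + 1L)
}

#' Generate a synthetic peak BED track
#'
#' Peaks centered on the given bins plus uniformly placed background
#' peaks, for boundary-enrichment tests.
#'
#' @param boundary_bins Bins (1-based) carrying planted peaks.
#' @param n_background Number of random background peaks.
#' @param binning The region's [genomic_binning()].
#' @param seed Integer seed.
#' @param path Optional path; if given the peaks are also written as BED.
#' @return A [GenomicRanges::GRanges] of peaks.
#' @export
generate_peaks <- function(boundary_bins, n_background, binning,
                           seed = 1L, path = NULL) {
  set.seed(seed)
  bg <- if (n_background > 0) sample.int(binning$n_bins, n_background,
                                         replace = TRUE) else integer(0)
  bins <- c(as.integer(boundary_bins), bg)
  if (!length(bins)) stop("no peaks requested")
  starts <- bin_starts(binning)[bins]
  gr <- GenomicRanges::GRanges(
    binning$chrom,
    IRanges::IRanges(start = starts + 1, width = binning$resolution),
    name = sprintf("peak%d", seq_along(bins)))
  if (!is.null(path)) rtracklayer::export(gr, path, format = "BED")
  gr
}
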