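#' Spatial distance map of a conformation
#'
#' @param conf A `conformation` or bare `n x 3` coordinate matrix.
#' @return Symmetric `n x n` matrix of Euclidean bead-bead distances (nm).
#' @export
distance_map <- function(conf) {
  x <- if (inherits(conf, "conformation")) conf$coords else conf
  as.matrix(dist(x))
}

#' Compactness of a conformation
#'
#' Radius of gyration (root-mean-square distance of beads from their
#' centroid) and end-to-end distance.
#'
#' @param conf A `conformation` or coordinate matrix.
#' @return List with `rg` and `end_to_end`, both in nm.
#' @export
compactness <- function(conf) {
  x <- if (inherits(conf, "conformation")) conf$coords else conf
  ctr <- colMeans(x)
  rg <- sqrt(mean(rowSums((x - rep(ctr, each = nrow(x)))^2)))
  e2e <- sqrt(sum((x[nrow(x), ] - x[1, ])^2))
  list(rg = rg, end_to_end = e2e)
}

ensemble_rg <- function(ensemble) {
  apply(ensemble$coords, 3, function(m) compactness(m)$rg)
}

#' Cluster conformations by their distance maps
#'
#' Hierarchical agglomerative clustering (Ward linkage, `"ward.D2"`) on
#' the vectorized upper-triangle spatial-distance maps, cut into `k`
#' clusters that are then relabeled 1..k by increasing weighted mean
#' radius of gyration, so cluster 1 is always the most compact.
#'
#' @param ensemble A `chain_ensemble`.
#' @param k Number of clusters (2 <= k <= number of chains).
#' @param d_c Ligation threshold for the per-cluster aggregated maps.
#' @return An object of class `conformation_clusters`: `assignments`
#'   (per chain), `proportions` (weighted, summing to 1), `mean_rg`
#'   (per cluster, increasing), and `maps` (per-cluster weighted contact
#'   maps; their proportion-weighted average is exactly the full-ensemble
#'   map).
#' @export
cluster_conformations <- function(ensemble, k,
                                  d_c = ensemble$params$ligation_threshold_nm) {
  N <- ensemble$n_chains
  if (k < 2 || k > N) stop("k must be in [2, n_chains]")
  V <- t(apply(ensemble$coords, 3, function(m) {
    dm <- as.matrix(dist(m)); dm[upper.tri(dm)]
  }))
  hc <- hclust(dist(V), method = "ward.D2")
  raw <- cutree(hc, k = k)
  rg <- ensemble_rg(ensemble)
  w <- ensemble$weights
  mean_rg_raw <- vapply(seq_len(k), function(c) {
    i <- raw == c; sum(w[i] * rg[i]) / sum(w[i])
  }, numeric(1))
  relabel <- order(mean_rg_raw)
  assignments <- match(raw, relabel)
  proportions <- vapply(seq_len(k), function(c)
    sum(w[assignments == c]) / sum(w), numeric(1))
  maps <- lapply(seq_len(k), function(c) {
    i <- assignments == c
    cpp_contact_map(ensemble$coords[, , i, drop = FALSE], w[i], d_c)
  })
  structure(list(assignments = assignments, proportions = proportions,
                 mean_rg = sort(mean_rg_raw), maps = maps, k = k,
                 hclust = hc),
            class = "conformation_clusters")
}

#' @export
print.conformation_clusters <- function(x, ...) {
  cat(sprintf("<conformation_clusters> k = %d\n", x$k))
  for (c in seq_len(x$k))
    cat(sprintf("  cluster %d: %.1f%% of weight, mean Rg %.1f nm\n",
                c, 100 * x$proportions[c], x$mean_rg[c]))
  invisible(x)
}

block_sums <- function(dmap) {
  # summed-area table: S[i+1, j+1] = sum(dmap[1:i, 1:j])
  n <- nrow(dmap)
  S <- matrix(0, n + 1, n + 1)
  # double cumsum comes out transposed from apply(); undo
  S[-1, -1] <- t(apply(apply(dmap, 2, cumsum), 1, cumsum))
  S
}

block_sum <- function(S, r1, r2, c1, c2) {
  S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
}

#' Boundary-strength curve of a distance map
#'
#' The spatial-distance ratio at each genomic position `i`: the mean
#' distance between the `w` bins upstream and the `w` bins starting at
#' `i`, divided by the average of the two within-window mean distances. A
#' position where the chain separates into two spatially distinct blocks
#' scores high; a position inside a homogeneous block scores near 1.
#' Positions closer than `w` to either end are padded with 1.
#'
#' @param dmap A spatial distance map (see [distance_map()]).
#' @param w Window size in bins (default 10; >= 2). `nrow(dmap)` must be
#'   at least `2 * w`.
#' @return Numeric vector of per-position strengths; position `i` scores
#'   the junction between bins `i - 1` and `i`.
#' @export
boundary_strength <- function(dmap, w = 10) {
  n <- nrow(dmap)
  stopifnot(w >= 2, n >= 2 * w)
  S <- block_sums(dmap)
  strength <- rep(1, n)
  for (i in (w + 1):(n - w + 1)) {
    l1 <- i - w; l2 <- i - 1
    r1 <- i; r2 <- i + w - 1
    inter <- block_sum(S, l1, l2, r1, r2) / (w * w)
    intra_l <- block_sum(S, l1, l2, l1, l2) / (w * (w - 1))
    intra_r <- block_sum(S, r1, r2, r1, r2) / (w * (w - 1))
    strength[i] <- inter / (0.5 * (intra_l + intra_r))
  }
  strength
}

#' Call single-cell domain boundaries from a strength curve
#'
#' Local maxima of the boundary-strength curve at or above `threshold`,
#' kept greedily in decreasing strength order subject to a minimum
#' pairwise separation (ties broken toward the lower position).
#'
#' @param strength Per-position strength curve.
#' @param threshold Minimum strength (default 2.2; must exceed 1).
#' @param min_sep Minimum separation between kept boundaries, bins.
#' @return Sorted integer vector of boundary positions.
#' @export
call_boundaries <- function(strength, threshold = 2.2, min_sep = 10) {
  stopifnot(threshold > 1)
  n <- length(strength)
  if (n < 3) return(integer(0))
  s <- strength
  is_max <- vapply(2:(n - 1), function(i)
    s[i] >= s[i - 1] && s[i] >= s[i + 1] && s[i] >= threshold, logical(1))
  cand <- (2:(n - 1))[is_max]
  # drop plateau duplicates: keep the first position of equal-value runs
  if (length(cand) > 1)
    cand <- cand[c(TRUE, !(diff(cand) == 1 &
                             s[cand[-1]] == s[cand[-length(cand)]]))]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-s[cand], cand)]
  kept <- integer(0)
  for (b in cand) {
    if (!length(kept) || all(abs(kept - b) >= min_sep)) kept <- c(kept, b)
  }
  sort(kept)
}

#' Identify TAD-like domains of one conformation
#'
#' Each interval between adjacent called boundaries (with the region ends
#' acting as flanking boundaries) is a candidate domain. A candidate is
#' accepted when its within-interval pairwise distances are significantly
#' smaller than the distances from the interval to its equal-width flanks
#' (one-sided Wilcoxon rank-sum), after Benjamini-Hochberg adjustment over
#' the candidates of the conformation at level `alpha`. A conformation
#' without internal boundaries contributes zero domains (the undivided
#' region is not counted), and intervals shorter than 3 bins are
#' untestable and skipped.
#'
#' @param dmap A spatial distance map.
#' @param boundaries Sorted boundary positions from [call_boundaries()].
#' @param alpha BH-FDR threshold (default 0.05).
#' @return An object of class `domain_calls`: data frame `domains`
#'   (start, end, p, q) of accepted intervals and `n_domains`.
#' @export
call_tad_like <- function(dmap, boundaries, alpha = 0.05) {
  n <- nrow(dmap)
  empty <- structure(list(domains = data.frame(start = integer(0),
                                               end = integer(0),
                                               p = numeric(0),
                                               q = numeric(0)),
                          n_domains = 0L),
                     class = "domain_calls")
  if (!length(boundaries)) return(empty)
  boundaries <- sort(boundaries)
  edges <- unique(c(1L, as.integer(boundaries), n + 1L))
  cand <- data.frame(start = edges[-length(edges)],
                     end = edges[-1] - 1L)
  cand <- cand[cand$end - cand$start + 1 >= 3, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  pv <- vapply(seq_len(nrow(cand)), function(r) {
    a <- cand$start[r]; b <- cand$end[r]
    len <- b - a + 1
    inside <- dmap[a:b, a:b][upper.tri(matrix(0, len, len))]
    lf <- if (a > 1) max(1, a - len):(a - 1) else integer(0)
    rf <- if (b < n) (b + 1):min(n, b + len) else integer(0)
    flank <- c(dmap[a:b, lf], dmap[a:b, rf])
    if (!length(flank)) return(NA_real_)
    suppressWarnings(wilcox.test(inside, flank,
                                 alternative = "less")$p.value)
  }, numeric(1))
  keep <- !is.na(pv)
  cand <- cand[keep, , drop = FALSE]
  pv <- pv[keep]
  if (!length(pv)) return(empty)
  qv <- p.adjust(pv, method = "BH")
  acc <- qv < alpha
  structure(list(domains = data.frame(start = cand$start[acc],
                                      end = cand$end[acc],
                                      p = pv[acc], q = qv[acc]),
                 n_domains = sum(acc)),
            class = "domain_calls")
}

#' @export
print.domain_calls <- function(x, ...) {
  cat(sprintf("<domain_calls> %d TAD-like domain(s)\n", x$n_domains))
  if (x$n_domains) print(x$domains)
  invisible(x)
}

single_cell_domains <- function(dmap, w = 10, threshold = 2.2,
                                min_sep = w, alpha = 0.05) {
  s <- boundary_strength(dmap, w)
  b <- call_boundaries(s, threshold, min_sep)
  list(strength = s, boundaries = b,
       tads = call_tad_like(dmap, b, alpha))
}

#' Per-bin boundary probability across an ensemble
#'
#' Samples conformations (with replacement, proportional to their
#' importance weights), calls boundaries and TAD-like domains in each, and
#' aggregates: the per-bin fraction of sampled conformations with a
#' boundary at that position, the histogram of per-conformation TAD-like
#' counts, and the fraction of conformations carrying at least one
#' TAD-like structure.
#'
#' @param ensemble A `chain_ensemble`.
#' @param sample_size Number of conformations to sample.
#' @param seed Integer seed (recorded in the result).
#' @param w,threshold,min_sep,alpha Boundary/domain calling parameters,
#'   see [boundary_strength()], [call_boundaries()], [call_tad_like()].
#' @return An object of class `boundary_probability`: `prob` (per bin),
#'   `histogram` (proportions by domain count, summing to 1),
#'   `frac_ge1`, and `seed`.
#' @export
boundary_probability <- function(ensemble, sample_size = 5000,
                                 seed = 1L, w = 10, threshold = 2.2,
                                 min_sep = w, alpha = 0.05) {
  n <- ensemble$n_beads
  set.seed(seed)
  idx <- sample.int(ensemble$n_chains, sample_size, replace = TRUE,
                    prob = ensemble$weights)
  counts <- integer(sample_size)
  hits <- numeric(n)
  for (s in seq_len(sample_size)) {
    dmap <- as.matrix(dist(ensemble$coords[, , idx[s]]))
    res <- single_cell_domains(dmap, w, threshold, min_sep, alpha)
    hits[res$boundaries] <- hits[res$boundaries] + 1
    counts[s] <- res$tads$n_domains
  }
  tab <- table(counts) / sample_size
  structure(list(prob = hits / sample_size,
                 histogram = setNames(as.numeric(tab), names(tab)),
                 frac_ge1 = mean(counts >= 1),
                 n_sampled = sample_size, seed = seed),
            class = "boundary_probability")
}

#' @export
print.boundary_probability <- function(x, ...) {
  cat(sprintf(paste0("<boundary_probability> %d conformations sampled; ",
                     "%.1f%% with >= 1 TAD-like domain\n"),
              x$n_sampled, 100 * x$frac_ge1))
  invisible(x)
}

#' Enrichment of a per-bin profile around peaks
#'
#' Averages the profile at each bin offset from the peak centers within
#' `flank_bp`, divided by the regional mean, giving a relative-position
#' enrichment curve (1 = no enrichment). Boundary probability is
#' strandless, so peaks on either strand are treated identically.
#'
#' @param profile Per-bin numeric vector (e.g. boundary probabilities).
#' @param peaks A [GenomicRanges::GRanges] of peaks.
#' @param binning The region's [genomic_binning()].
#' @param flank_bp Half-width of the window around peak centers (bp).
#' @return Data frame with `offset_bp` and `enrichment`.
#' @export
peak_enrichment <- function(profile, peaks, binning,
                            flank_bp = 10 * binning$resolution) {
  n <- binning$n_bins
  stopifnot(length(profile) == n)
  mid <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2
  ctr_bin <- floor((mid - binning$start) / binning$resolution) + 1
  ctr_bin <- ctr_bin[ctr_bin >= 1 & ctr_bin <= n &
                       as.character(GenomicRanges::seqnames(peaks)) ==
                         binning$chrom]
  if (!length(ctr_bin)) stop("no usable peaks")
  fb <- floor(flank_bp / binning$resolution)
  offs <- -fb:fb
  gmean <- mean(profile)
  enr <- vapply(offs, function(o) {
    pos <- ctr_bin + o
    pos <- pos[pos >= 1 & pos <= n]
    if (!length(pos)) return(NA_real_)
    mean(profile[pos]) / gmean
  }, numeric(1))
  data.frame(offset_bp = offs * binning$resolution, enrichment = enr)
}

#' Virtual 4C track of a pair map
#'
#' The anchor row of a symmetric pair map, viewed as a 1D genomic track
#' (the mean over anchor bins when the anchor is an interval).
#'
#' @param map Symmetric matrix (propensities, calls, contact
#'   probabilities, ...).
#' @param anchor Bin index or vector of bin indices (1-based).
#' @return Numeric per-bin track.
#' @export
virtual_4c <- function(map, anchor) {
  n <- nrow(map)
  anchor <- as.integer(anchor)
  if (any(anchor < 1 | anchor > n)) stop("anchor outside region")
  if (length(anchor) == 1) map[anchor, ] else colMeans(map[anchor, ,
                                                           drop = FALSE])
}

loci_min_dist <- function(coords, locus_a, locus_b) {
  # minimal bead-bead distance between two loci (bead index sets)
  d2 <- outer(rowSums(coords[locus_a, , drop = FALSE]^2),
              rowSums(coords[locus_b, , drop = FALSE]^2), "+") -
    2 * coords[locus_a, , drop = FALSE] %*%
    t(coords[locus_b, , drop = FALSE])
  sqrt(max(0, min(d2)))
}

#' Many-body contact fraction of a set of loci
#'
#' The weighted fraction of conformations in which all pairwise distances
#' among the loci are below the ligation threshold (for a pair of
#' single-bin loci this equals the simulated contact map entry exactly).
#' Loci spanning several bins use the minimal bead-bead distance. With
#' `condition = c(a, b)` the fraction is computed among conformations
#' already satisfying the contact between loci `a` and `b`; if no
#' conformation satisfies the condition the fraction is undefined (`NA`
#' with a warning).
#'
#' @param ensemble A `chain_ensemble`.
#' @param loci List of >= 2 loci, each a vector of bead indices.
#' @param d_c Ligation threshold (nm).
#' @param condition Optional pair of locus indices conditioning the
#'   fraction.
#' @return List with `fraction`, and `distances`: one numeric vector of
#'   per-conformation distances per locus pair (named `"a-b"`).
#' @export
multibody_fraction <- function(ensemble, loci,
                               d_c = ensemble$params$ligation_threshold_nm,
                               condition = NULL) {
  stopifnot(length(loci) >= 2)
  N <- ensemble$n_chains
  np <- utils::combn(length(loci), 2)
  D <- matrix(NA_real_, N, ncol(np))
  for (k in seq_len(N)) {
    x <- ensemble$coords[, , k]
    for (p in seq_len(ncol(np)))
      D[k, p] <- loci_min_dist(x, loci[[np[1, p]]], loci[[np[2, p]]])
  }
  w <- ensemble$weights / sum(ensemble$weights)
  all_contact <- rowSums(D < d_c) == ncol(np)
  if (is.null(condition)) {
    frac <- sum(w[all_contact])
  } else {
    stopifnot(length(condition) == 2)
    pcol <- which(np[1, ] == min(condition) & np[2, ] == max(condition))
    cond <- D[, pcol] < d_c
    if (!any(cond)) {
      warning("condition never met; fraction undefined")
      frac <- NA_real_
    } else {
      frac <- sum(w[cond & all_contact]) / sum(w[cond])
    }
  }
  dists <- lapply(seq_len(ncol(np)), function(p) D[, p])
  names(dists) <- apply(np, 2, paste, collapse = "-")
  list(fraction = frac, distances = dists)
}
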