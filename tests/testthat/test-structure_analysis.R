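test_that("distance maps are metric and match hand geometry", {
  two <- rbind(c(0, 0, 0), c(25, 0, 0))
  expect_equal(distance_map(two), matrix(c(0, 25, 25, 0), 2),
               ignore_attr = TRUE)
  collinear <- rbind(c(0, 0, 0), c(25, 0, 0), c(50, 0, 0))
  expect_equal(distance_map(collinear)[1, 3], 50)
  # triangle inequality on random conformations
  p <- physical_params(confinement_radius_nm = 150)
  ens <- build_null_ensemble(growth_config(12, 5, master_seed = 1), p)
  for (k in 1:5) {
    d <- distance_map(ens$coords[, , k])
    for (i in 1:12) for (j in 1:12) {
      expect_true(all(d[i, j] <= d[i, ] + d[, j] + 1e-9))
    }
  }
})

test_that("compactness matches closed forms", {
  two <- rbind(c(0, 0, 0), c(30, 0, 0))
  cs <- compactness(two)
  expect_equal(cs$rg, 15)
  expect_equal(cs$end_to_end, 30)
  expect_equal(compactness(matrix(5, 4, 3))$rg, 0)
  # m points on a circle of radius R have rg exactly R
  R <- 120
  ang <- 2 * pi * (0:11) / 12
  ring <- cbind(R * cos(ang), R * sin(ang), 0)
  expect_equal(compactness(ring)$rg, R)
})

test_that("clustering splits and orders conformations by compactness", {
  set.seed(3)
  tight <- matrix(rnorm(30 * 3, sd = 5), 30)
  loose <- matrix(rnorm(30 * 3, sd = 80), 30)
  ens <- as_ensemble(list(tight, tight, loose, loose))
  cl <- cluster_conformations(ens, 2, d_c = 80)
  expect_equal(cl$assignments[1], cl$assignments[2])
  expect_equal(cl$assignments[3], cl$assignments[4])
  expect_false(cl$assignments[1] == cl$assignments[3])
  # cluster 1 is the most compact and proportions sum to one
  expect_equal(cl$assignments[1], 1L)
  expect_true(all(diff(cl$mean_rg) > 0))
  expect_equal(sum(cl$proportions), 1)
  # aggregated cluster maps average back to the full-ensemble map exactly
  full <- simulate_contact_map(ens, d_c = 80)
  back <- cl$proportions[1] * cl$maps[[1]] + cl$proportions[2] * cl$maps[[2]]
  expect_equal(back, full, tolerance = 1e-12)
  expect_error(cluster_conformations(ens, 9), "k must be")
})

test_that("boundary strength matches a direct computation", {
  set.seed(8)
  x <- matrix(rnorm(18), 6)
  dm <- distance_map(x)
  w <- 2
  got <- boundary_strength(dm, w)
  # direct double-loop evaluation, independent of the summed-area tables
  for (i in (w + 1):(6 - w + 1)) {
    left <- (i - w):(i - 1); right <- i:(i + w - 1)
    inter <- mean(dm[left, right])
    intra <- function(ix) mean(dm[ix, ix][upper.tri(dm[ix, ix])])
    expect_equal(got[i], inter / (0.5 * (intra(left) + intra(right))))
  }
  expect_equal(got[c(1, 2, 6)], c(1, 1, 1))
})

test_that("rigid well-separated globules peak above threshold at the junction", {
  set.seed(9)
  w <- 5
  x <- two_cluster_coords(2 * w, w + 1, sep = 300, spread = 3)
  s <- boundary_strength(distance_map(x), w)
  expect_gt(s[w + 1], 2.2)
  expect_equal(which.max(s), w + 1)
  # a single tight globule has no interior maximum above threshold
  g <- matrix(runif(30 * 3, -20, 20), 30)
  sg <- boundary_strength(distance_map(g), 5)
  expect_true(all(sg[6:25] < 2.2))
  # a uniform straight rod has an essentially flat interior profile
  rod <- cbind(25 * (1:40), 0, 0)
  sr <- boundary_strength(distance_map(rod), 10)
  interior <- sr[11:30]
  expect_lt(diff(range(interior)), 1e-6)
})

test_that("boundary calling keeps separated local maxima above threshold", {
  flat <- rep(1, 100)
  expect_equal(call_boundaries(flat, 2.2, 10), integer(0))
  spike <- rep(1, 100); spike[50] <- 3
  expect_equal(call_boundaries(spike, 2.2, 10), 50L)
  two <- rep(1, 100); two[40] <- 3; two[43] <- 2.8
  expect_equal(call_boundaries(two, 2.2, min_sep = 5), 40L)
  expect_equal(sort(call_boundaries(two, 2.2, min_sep = 2)), c(40L, 43L))
  expect_error(call_boundaries(flat, threshold = 1), "threshold")
})

test_that("TAD-like calling accepts planted domains and skips degenerate input", {
  gp <- generate_labeled_conformations("globule-pair", n = 4, seed = 7)
  w <- round(gp$ensemble$n_beads / 5)
  for (k in 1:4) {
    dm <- distance_map(gp$ensemble$coords[, , k])
    res <- chromogrow:::single_cell_domains(dm, w, 2.2, w, 0.05)
    expect_equal(res$tads$n_domains, 2)
    expect_true(all(res$tads$domains$q < 0.05))
  }
  # no boundaries: the undivided region is not a domain
  dm <- distance_map(gp$ensemble$coords[, , 1])
  expect_equal(call_tad_like(dm, integer(0))$n_domains, 0)
  # intervals shorter than 3 bins are untestable
  res2 <- call_tad_like(dm, c(2, 4))
  expect_true(all(res2$domains$start != 2))
})

test_that("boundary probability concentrates where boundaries live", {
  gp <- generate_labeled_conformations("globule-pair", n = 1, seed = 3)
  n <- gp$ensemble$n_beads
  w <- round(n / 5)
  ens <- as_ensemble(rep(list(gp$ensemble$coords[, , 1]), 20),
                     params = gp$ensemble$params)
  bp <- boundary_probability(ens, sample_size = 50, seed = 5, w = w,
                             min_sep = w)
  expect_equal(sum(bp$prob > 0), 1)         # a single recurring boundary
  expect_equal(max(bp$prob), 1)
  expect_lte(abs(which.max(bp$prob) - gp$junction), 2)
  expect_equal(sum(bp$histogram), 1)
  expect_equal(bp$frac_ge1, 1)
})

test_that("boundary sites drawn uniformly from four positions recover 1/4 each", {
  set.seed(12)
  n <- 60
  sites <- c(15, 25, 35, 45)
  confs <- lapply(1:400, function(k)
    two_cluster_coords(n, sample(sites, 1), sep = 400, spread = 3))
  ens <- as_ensemble(confs)
  bp <- boundary_probability(ens, sample_size = 5000, seed = 6, w = 10,
                             min_sep = 10)
  for (s in sites) {
    expect_lt(abs(sum(bp$prob[(s - 1):(s + 1)]) - 0.25), 0.03)
  }
})

test_that("peak enrichment normalizes by the regional mean", {
  bn <- genomic_binning("chrT", 0, 2000, 60)
  flat <- rep(0.2, 60)
  pk <- generate_peaks(c(10, 30), 0, bn, seed = 1)
  en <- peak_enrichment(flat, pk, bn, flank_bp = 10000)
  expect_true(all(abs(en$enrichment - 1) < 1e-12))
  delta <- rep(0, 60); delta[c(10, 30)] <- 1
  en2 <- peak_enrichment(delta, pk, bn, flank_bp = 10000)
  expect_equal(which.max(en2$enrichment), which(en2$offset_bp == 0))
  expect_error(peak_enrichment(flat, generate_peaks(10, 0,
    genomic_binning("other", 0, 2000, 60), seed = 2), bn), "no usable peaks")
})

test_that("virtual 4C extracts anchor rows", {
  set.seed(5)
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2
  expect_equal(virtual_4c(m, 3), m[3, ])
  expect_equal(virtual_4c(m, c(2, 4)), colMeans(m[c(2, 4), ]))
  for (j in 1:8) expect_equal(virtual_4c(m, 3)[j], virtual_4c(m, j)[3])
  expect_error(virtual_4c(m, 9), "anchor")
})

test_that("multibody fractions handle three-way and conditional queries", {
  # two conformations: in one, loci 1/5/9 mutually close; in the other, far
  near <- two_cluster_coords(10, 11, sep = 0, spread = 5)   # one tight blob
  far <- cbind(200 * (1:10), 0, 0)
  ens <- as_ensemble(list(near, far))
  mb <- multibody_fraction(ens, list(1, 5, 9), d_c = 80)
  expect_equal(mb$fraction, 0.5)
  expect_length(mb$distances, 3)
  # conditional on a pair that is satisfied only in the blob
  mbc <- multibody_fraction(ens, list(1, 5, 9), d_c = 80, condition = c(1, 2))
  expect_equal(mbc$fraction, 1)
  # conditional never met
  expect_warning(
    mbn <- multibody_fraction(as_ensemble(list(far)), list(1, 5, 9),
                              d_c = 80, condition = c(1, 2)),
    "never met")
  expect_true(is.na(mbn$fraction))
})
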