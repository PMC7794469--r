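#' Contour length of chromatin per bead
#'
#' With a beads-on-string fiber of mass density `density` bp/nm, a bead of
#' `resolution_bp` base pairs spans `resolution_bp / density` nm of contour.
#' At the default density of 165 bp / 11 nm, a 2 kb bead corresponds to
#' about 133.3 nm of fiber packed into a 25 nm sphere.
#'
#' @param resolution_bp Base pairs per bead.
#' @param density Fiber mass density in bp per nm (default `165/11`).
#' @return Contour length per bead in nm.
#' @export
derive_geometry <- function(resolution_bp, density = 165 / 11) {
  stopifnot(resolution_bp > 0, density > 0)
  resolution_bp / density
}

#' Confinement radius for a modeled region
#'
#' The spherical volume confining the polymer is proportional to the
#' nuclear volume, scaled by the fraction of the (ploidy-adjusted) genome
#' the region represents: `V = V_nuc * region / genome`, and the radius is
#' `(3V / 4 pi)^(1/3)`.
#'
#' @param nuclear_volume_um3 Nuclear volume in cubic micrometres.
#' @param genome_size_mb Total genome size in Mb (ploidy-adjusted).
#' @param region_length_mb Length of the modeled region in Mb.
#' @return Confinement radius in nm.
#' @examples
#' derive_confinement(292, 700, 4) # S2R+, 4 Mb region: ~736 nm
#' @export
derive_confinement <- function(nuclear_volume_um3, genome_size_mb,
                               region_length_mb) {
  stopifnot(nuclear_volume_um3 > 0, genome_size_mb > 0,
            region_length_mb > 0, region_length_mb <= genome_size_mb)
  v_nm3 <- nuclear_volume_um3 * 1e9 * region_length_mb / genome_size_mb
  (3 * v_nm3 / (4 * pi))^(1 / 3)
}

#' Physical parameters of cell types
#'
#' Nuclear volume (um^3) and ploidy-adjusted genome size (Mb) presets:
#' `pre-mbt` (early embryo, nuclear cycles 9-13; 335 um^3, diploid 350 Mb),
#' `post-mbt` (embryo stages 5-8; 524 um^3, 350 Mb), and `s2r+`
#' (late-embryo-derived cell line; 292 um^3, tetraploid 700 Mb).
#'
#' @param cell One of `"pre-mbt"`, `"post-mbt"`, `"s2r+"`.
#' @return List with `nuclear_volume_um3` and `genome_size_mb`.
#' @export
cell_preset <- function(cell = c("pre-mbt", "post-mbt", "s2r+")) {
  cell <- match.arg(cell)
  switch(cell,
         "pre-mbt"  = list(nuclear_volume_um3 = 335, genome_size_mb = 350),
         "post-mbt" = list(nuclear_volume_um3 = 524, genome_size_mb = 350),
         "s2r+"     = list(nuclear_volume_um3 = 292, genome_size_mb = 700))
}

#' Physical polymer parameters
#'
#' Bundles the bead geometry, the contact (ligation) criterion, and the
#' nuclear confinement of the polymer model. The chromatin fiber is a
#' tangent-sphere chain: consecutive bead centers sit exactly one bead
#' diameter apart, non-adjacent centers may not come closer than one
#' diameter (excluded volume), and all centers stay within the confinement
#' sphere. The bead diameter defaults to 25 nm; the ligation threshold
#' `d_c` (80 nm) is the largest center-to-center distance at which a pair
#' is considered available for Hi-C ligation.
#'
#' Instead of `nuclear_volume_um3`/`genome_size_mb`/`region_length_mb`, the
#' confinement radius may be given directly via `confinement_radius_nm`
#' (used by fixtures and small test systems).
#'
#' @param resolution_bp Base pairs per bead (e.g. 2000 or 5000).
#' @param bead_diameter_nm Bead diameter, nm.
#' @param fiber_density Fiber mass density, bp per nm.
#' @param ligation_threshold_nm Contact threshold `d_c`, nm.
#' @param nuclear_volume_um3,genome_size_mb,region_length_mb Confinement
#'   inputs, see [derive_confinement()].
#' @param confinement_radius_nm Direct radius override, nm.
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(resolution_bp = 2000, bead_diameter_nm = 25,
                            fiber_density = 165 / 11,
                            ligation_threshold_nm = 80,
                            nuclear_volume_um3 = NULL,
                            genome_size_mb = NULL,
                            region_length_mb = NULL,
                            confinement_radius_nm = NULL) {
  stopifnot(bead_diameter_nm > 0,
            ligation_threshold_nm >= bead_diameter_nm)
  if (is.null(confinement_radius_nm)) {
    stopifnot(!is.null(nuclear_volume_um3), !is.null(genome_size_mb),
              !is.null(region_length_mb))
    confinement_radius_nm <- derive_confinement(
      nuclear_volume_um3, genome_size_mb, region_length_mb)
  }
  structure(list(resolution_bp = resolution_bp,
                 bead_diameter_nm = bead_diameter_nm,
                 fiber_density = fiber_density,
                 ligation_threshold_nm = ligation_threshold_nm,
                 nuclear_volume_um3 = nuclear_volume_um3,
                 genome_size_mb = genome_size_mb,
                 region_length_mb = region_length_mb,
                 confinement_radius_nm = confinement_radius_nm,
                 contour_per_bead_nm = derive_geometry(resolution_bp,
                                                       fiber_density)),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat(sprintf(paste0("<physical_params> %d bp/bead, bead %g nm, d_c %g nm, ",
                     "confinement radius %.1f nm\n"),
              x$resolution_bp, x$bead_diameter_nm, x$ligation_threshold_nm,
              x$confinement_radius_nm))
  invisible(x)
}

new_conformation <- function(coords, weight = 1, rng_seed = NA_integer_) {
  structure(list(coords = coords, weight = weight, rng_seed = rng_seed),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads, weight %.4g\n", nrow(x$coords),
              x$weight))
  invisible(x)
}

new_chain_ensemble <- function(coords, weights, params, kind, provenance) {
  structure(list(coords = coords, weights = weights, params = params,
                 kind = kind, n_chains = dim(coords)[3],
                 n_beads = dim(coords)[1], provenance = provenance),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  ess <- sum(x$weights)^2 / sum(x$weights^2)
  cat(sprintf("<chain_ensemble> %s: %d chains x %d beads, ESS %.0f\n",
              x$kind, x$n_chains, x$n_beads, ess))
  invisible(x)
}

#' @export
summary.chain_ensemble <- function(object, ...) {
  rg <- apply(object$coords, 3, function(m) {
    c <- colMeans(m); sqrt(mean(rowSums((m - rep(c, each = nrow(m)))^2)))
  })
  w <- object$weights / sum(object$weights)
  out <- list(kind = object$kind, n_chains = object$n_chains,
              n_beads = object$n_beads,
              ess = 1 / sum(w^2),
              mean_rg = sum(w * rg),
              params = object$params)
  class(out) <- "summary.chain_ensemble"
  out
}

#' @export
print.summary.chain_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<chain_ensemble> %s\n  chains: %d x %d beads\n",
                     "  effective sample size: %.0f\n",
                     "  weighted mean radius of gyration: %.1f nm\n"),
              x$kind, x$n_chains, x$n_beads, x$ess, x$mean_rg))
  invisible(x)
}

#' Extract one conformation from an ensemble
#'
#' @param ensemble A `chain_ensemble`.
#' @param k Chain index.
#' @export
get_conformation <- function(ensemble, k) {
  stopifnot(k >= 1, k <= ensemble$n_chains)
  new_conformation(matrix(ensemble$coords[, , k], ncol = 3),
                   ensemble$weights[k])
}

#' Validate the physical invariants of a conformation
#'
#' Checks that consecutive beads sit exactly one bead diameter apart
#' (within 1e-6 nm), that non-adjacent bead centers are at least one
#' diameter apart, and that every bead lies inside the confinement sphere.
#'
#' @param conf A `conformation` (or a bare `n x 3` coordinate matrix).
#' @param params A `physical_params`.
#' @return List with per-invariant `pass` and the first violating index
#'   (bond: bead index; self-avoidance: pair; confinement: bead index),
#'   plus overall `pass`.
#' @export
validate_conformation <- function(conf, params) {
  x <- if (inherits(conf, "conformation")) conf$coords else conf
  n <- nrow(x)
  b <- params$bead_diameter_nm
  tol <- 1e-6
  bond <- list(pass = TRUE, first = NULL)
  if (n >= 2) {
    d <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
    bad <- which(abs(d - b) > tol)
    if (length(bad)) bond <- list(pass = FALSE, first = bad[1])
  }
  avoid <- list(pass = TRUE, first = NULL)
  if (n >= 3) {
    dm <- as.matrix(dist(x))
    dm[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- Inf
    dm[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- Inf
    diag(dm) <- Inf
    viol <- which(dm < b - tol, arr.ind = TRUE)
    if (nrow(viol))
      avoid <- list(pass = FALSE, first = unname(sort(viol[1, ])))
  }
  conf_ok <- list(pass = TRUE, first = NULL)
  r <- sqrt(rowSums(x^2))
  bad <- which(r > params$confinement_radius_nm + tol)
  if (length(bad)) conf_ok <- list(pass = FALSE, first = bad[1])
  list(pass = bond$pass && avoid$pass && conf_ok$pass,
       bond = bond, self_avoidance = avoid, confinement = conf_ok)
}

#' Validate every chain of an ensemble
#'
#' @param ensemble A `chain_ensemble`.
#' @param params Defaults to the ensemble's own parameters.
#' @return Logical vector, one entry per chain.
#' @export
validate_ensemble <- function(ensemble, params = ensemble$params) {
  vapply(seq_len(ensemble$n_chains), function(k)
    validate_conformation(ensemble$coords[, , k], params)$pass, logical(1))
}

#' Export an ensemble as multi-record XYZ text
#'
#' One record per conformation: a bead-count line, a comment line carrying
#' the chain index and importance weight, then one `index x y z` line per
#' bead (nm). Readable by standard molecular viewers after trivial
#' reformatting and by [read.table()].
#'
#' @param ensemble A `chain_ensemble`.
#' @param path Output path.
#' @export
write_xyz <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(ensemble$n_chains)) {
    m <- ensemble$coords[, , k]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("chain %d weight %.8g", k, ensemble$weights[k]), con)
    writeLines(sprintf("%d %.4f %.4f %.4f", seq_len(nrow(m)),
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
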