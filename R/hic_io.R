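#' Genomic binning of a region
#'
#' Describes the partition of a genomic region into equal-width bins. Bin `i`
#' (1-based in R; files using 0-based indices are converted on read) covers
#' the half-open interval `[start + (i-1)*resolution, start + i*resolution)`.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start coordinate of the region in bp.
#' @param resolution Bin width in bp.
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `genomic_binning`.
#' @examples
#' genomic_binning("chr2L", 11e6, 2000, 500)
#' @export
genomic_binning <- function(chrom, start, resolution, n_bins) {
  stopifnot(resolution > 0, n_bins >= 2, start >= 0)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 resolution = as.numeric(resolution),
                 n_bins = as.integer(n_bins)),
            class = "genomic_binning")
}

#' Binning derived from a region's span
#'
#' Number of bins is the region length divided by the resolution; a 4 Mb
#' region at 2 kb resolution yields exactly 2000 bins/beads.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region coordinates (bp).
#' @param resolution Bin width (bp).
#' @export
binning_from_region <- function(chrom, start, end, resolution) {
  stopifnot(end > start, resolution > 0)
  genomic_binning(chrom, start, resolution,
                  as.integer(ceiling((end - start) / resolution)))
}

#' @export
print.genomic_binning <- function(x, ...) {
  cat(sprintf("<genomic_binning> %s:%d-%d, %d bins @ %d bp\n", x$chrom,
              as.integer(x$start),
              as.integer(x$start + x$n_bins * x$resolution),
              x$n_bins, as.integer(x$resolution)))
  invisible(x)
}

bin_starts <- function(binning) {
  binning$start + (seq_len(binning$n_bins) - 1) * binning$resolution
}

new_contact_matrix <- function(counts, binning, balanced = FALSE,
                               mask = NULL, converged = NA) {
  if (is.null(mask)) mask <- rep(FALSE, nrow(counts))
  structure(list(counts = counts, binning = binning, balanced = balanced,
                 mask = mask, converged = converged),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d bins, %s, %d masked, total %.4g\n",
              nrow(x$counts), ncol(x$counts),
              if (x$balanced) "balanced" else "raw", sum(x$mask),
              sum(x$counts)))
  invisible(x)
}

check_symmetric <- function(m, tol = 1e-8) {
  max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Read a binned Hi-C contact matrix
#'
#' Reads either a dense tab-separated matrix (no header) or sparse
#' bin-bin-count triplets with 0-based bin indices. Triplet input is
#' symmetrized by mirroring each `(i, j)` entry into `(j, i)`; pairs absent
#' from the file are zero. Dense input must already be symmetric.
#'
#' @param path Path to the file.
#' @param format `"dense-tsv"` or `"coo-triplet"`.
#' @param binning A [genomic_binning()] giving the expected dimensions.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, format = c("dense-tsv", "coo-triplet"),
                                binning) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  n <- binning$n_bins
  if (format == "dense-tsv") {
    m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("matrix is %dx%d but binning has %d bins",
                   nrow(m), ncol(m), n))
    if (!check_symmetric(m)) stop("matrix not symmetric")
  } else {
    tr <- read.table(path, sep = "\t", header = FALSE)
    if (ncol(tr) < 3) stop("COO input needs 3 columns: bin_i bin_j count")
    i <- as.integer(tr[[1]]); j <- as.integer(tr[[2]]); v <- as.numeric(tr[[3]])
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("negative count at line %d", bad[1]))
    bad <- which(i < 0 | i >= n | j < 0 | j >= n)
    if (length(bad))
      stop(sprintf("bin index out of range (n_bins = %d) at line %d",
                   n, bad[1]))
    m <- matrix(0, n, n)
    for (r in seq_along(i)) {
      m[i[r] + 1L, j[r] + 1L] <- m[i[r] + 1L, j[r] + 1L] + v[r]
      if (i[r] != j[r]) m[j[r] + 1L, i[r] + 1L] <- m[j[r] + 1L, i[r] + 1L] + v[r]
    }
  }
  if (any(!is.finite(m))) stop("non-finite entries in contact matrix")
  if (any(m < 0)) stop("negative entries in contact matrix")
  new_contact_matrix(m, binning)
}

#' Write a contact matrix
#'
#' `dense-tsv` writes the full matrix; `coo-triplet` writes nonzero
#' upper-triangle (including diagonal) entries with 0-based indices, the
#' exact inverse of [read_contact_matrix()]'s mirroring.
#'
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @param format `"dense-tsv"` or `"coo-triplet"`.
#' @export
write_contact_matrix <- function(cm, path,
                                 format = c("dense-tsv", "coo-triplet")) {
  format <- match.arg(format)
  m <- cm$counts
  if (format == "dense-tsv") {
    write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                     count = m[idx])
    write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Iterative correction (ICE) of a Hi-C matrix
#'
#' Matrix balancing by iterative correction: rows and columns are rescaled
#' until every non-masked row sum is within `tol` of the mean row sum.
#' Bins with zero raw marginal, or with marginal below the
#' `mask_quantile` quantile of the nonzero marginals, are masked and
#' excluded from balancing (their rows/columns are zeroed).
#'
#' @param cm A raw `contact_matrix`.
#' @param max_iter Maximum number of sweeps.
#' @param tol Relative tolerance on row-sum deviation from the mean.
#' @param mask_quantile Low-coverage quantile to mask (default 0.02, i.e. the lowest 2 percent).
#' @return A balanced `contact_matrix` with `mask` and `converged` set; the
#'   total count of the non-masked submatrix is preserved. Warns (and sets
#'   `converged = FALSE`) on non-convergence.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5,
                        mask_quantile = 0.02) {
  stopifnot(tol > 0, !isTRUE(cm$balanced))
  m <- cm$counts
  marg <- rowSums(m)
  mask <- marg == 0
  if (mask_quantile > 0 && any(!mask)) {
    thr <- quantile(marg[!mask], mask_quantile)
    mask <- mask | (marg < thr)
  }
  if (all(mask)) stop("all bins masked; no signal to balance")
  keep <- which(!mask)
  w <- m[keep, keep, drop = FALSE]
  total <- sum(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    if (any(s == 0)) stop("zero marginal appeared during balancing")
    delta <- s / mean(s)
    if (max(abs(delta - 1)) < tol) { converged <- TRUE; break }
    w <- w / outer(delta, delta)
  }
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations", max_iter))
  w <- w * (total / sum(w))
  out <- matrix(0, nrow(m), ncol(m))
  out[keep, keep] <- w
  new_contact_matrix(out, cm$binning, balanced = TRUE, mask = mask,
                     converged = converged)
}

#' Hi-C contact propensities
#'
#' Normalizes a contact matrix by the mean contact frequency of adjacent
#' bins, on the assumption that neighboring regions always form Hi-C
#' ligations: `p_obs(i, j) = C(i, j) / E_diag(1)`, where `E_diag(1)` is the
#' mean of `C` over non-masked pairs at distance one bin. The mean
#' propensity on the first off-diagonal is therefore exactly 1, and the
#' result is invariant to overall scaling of the counts. Masked bins
#' propagate as `NA`.
#'
#' @param cm A `contact_matrix` (typically ICE-balanced).
#' @return An object of class `propensity_map` with fields `p_obs`,
#'   `e_diag1`, `mask`, `binning`.
#' @export
compute_propensity <- function(cm) {
  m <- cm$counts
  n <- nrow(m)
  mask <- cm$mask
  adj <- vapply(seq_len(n - 1), function(i) {
    if (mask[i] || mask[i + 1]) NA_real_ else m[i, i + 1]
  }, numeric(1))
  adj <- adj[!is.na(adj)]
  if (!length(adj) || !any(adj > 0)) stop("no adjacent-bin signal")
  e1 <- mean(adj)
  if (e1 == 0) stop("no adjacent-bin signal")
  p <- m / e1
  p[mask, ] <- NA_real_
  p[, mask] <- NA_real_
  structure(list(p_obs = p, e_diag1 = e1, mask = mask,
                 binning = cm$binning),
            class = "propensity_map")
}

#' @export
print.propensity_map <- function(x, ...) {
  cat(sprintf("<propensity_map> %d bins, E_diag(1) = %.4g, %d masked\n",
              nrow(x$p_obs), x$e_diag1, sum(x$mask)))
  invisible(x)
}

#' Read a BED file of intervals
#'
#' Thin wrapper over `rtracklayer::import()`; BED's 0-based half-open
#' convention is converted to the 1-based `GRanges` convention on read.
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a per-bin track as bedGraph
#'
#' @param values Numeric vector, one value per bin.
#' @param binning The region's [genomic_binning()].
#' @param path Output path.
#' @export
write_bedgraph <- function(values, binning, path) {
  stopifnot(length(values) == binning$n_bins)
  starts <- bin_starts(binning)
  gr <- GenomicRanges::GRanges(
    binning$chrom,
    IRanges::IRanges(start = starts + 1, width = binning$resolution),
    score = as.numeric(values))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
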