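ut_pairs <- function(n) {
  # upper-triangle pair indices in column-major (upper.tri) order,
  # matching the row order of cpp_contact_indicators()
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Bootstrap configuration for significance testing
#'
#' Bag of Little Bootstraps (BLB): `n_subsets` small subsets of
#' `subset_size` chains are drawn from the ensemble without replacement;
#' each subset is resampled up to the full ensemble size `M / n_subsets`
#' times (remainder distributed deterministically over the first subsets),
#' for a total of `n_replicates` bootstrap ensembles.
#'
#' @param n_replicates Total bootstrap replicates M (>= 100).
#' @param subset_size Chains per subset b; default the smaller of 1300 and
#'   1 percent of the ensemble (at least 100), resolved when the ensemble is seen.
#' @param n_subsets Number of subsets s.
#' @param seed Integer seed for subset and resampling draws.
#' @export
bootstrap_config <- function(n_replicates = 5000, subset_size = NULL,
                             n_subsets = 4, seed = 1L) {
  stopifnot(n_replicates >= 100, n_subsets >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 subset_size = if (is.null(subset_size)) NULL
                               else as.integer(subset_size),
                 n_subsets = as.integer(n_subsets),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

resolve_subset_size <- function(config, n_chains) {
  b <- config$subset_size
  if (is.null(b)) b <- min(1300L, max(100L, ceiling(0.01 * n_chains)))
  b <- min(b, n_chains)
  as.integer(b)
}

#' BLB replicate contact-probability maps
#'
#' Draws the BLB subsets and, from each, multinomial resamples of the full
#' ensemble size whose counts act as weights in the contact-probability
#' formula, yielding one random-collision map per replicate.
#'
#' @param ensemble The null `chain_ensemble`.
#' @param config A [bootstrap_config()].
#' @param d_c Ligation threshold (nm).
#' @return A matrix of replicate `p_null` values, one row per
#'   upper-triangle bin pair (in [upper.tri()] column-major order), one
#'   column per replicate; pair indices in attribute `pairs`.
#' @export
blb_replicates <- function(ensemble, config,
                           d_c = ensemble$params$ligation_threshold_nm) {
  N <- ensemble$n_chains
  b <- resolve_subset_size(config, N)
  s <- config$n_subsets
  M <- config$n_replicates
  stopifnot(b <= N)
  set.seed(config$seed)
  per <- rep(M %/% s, s)
  if (M %% s > 0) per[seq_len(M %% s)] <- per[seq_len(M %% s)] + 1L
  if (s * b <= N) {
    perm <- sample.int(N)
    subsets <- lapply(seq_len(s), function(i) perm[((i - 1) * b + 1):(i * b)])
  } else {
    subsets <- lapply(seq_len(s), function(i) sample.int(N, b))
  }
  n <- ensemble$n_beads
  out <- matrix(NA_real_, n * (n - 1) / 2, M)
  col <- 1L
  for (i in seq_len(s)) {
    idx <- subsets[[i]]
    I <- cpp_contact_indicators(ensemble$coords[, , idx, drop = FALSE], d_c)
    w <- ensemble$weights[idx]
    for (r in seq_len(per[i])) {
      cnt <- as.numeric(rmultinom(1, N, w / sum(w)))
      out[, col] <- as.numeric(I %*% cnt) / N
      col <- col + 1L
    }
  }
  attr(out, "pairs") <- ut_pairs(n)
  out
}

#' Quantile normalization onto a pooled reference
#'
#' Maps the ranks of each replicate map and of the observed propensities
#' onto a common reference distribution, the mean sorted vector across all
#' columns (replicates plus observed). Ranks within each map are preserved
#' exactly. All-constant columns pass through unchanged.
#'
#' @param replicates Matrix of replicate values (rows = pairs, columns =
#'   replicates).
#' @param p_obs Numeric vector of observed propensities on the same pairs.
#' @return List with `replicates` and `p_obs`, normalized.
#' @export
quantile_normalize <- function(replicates, p_obs) {
  stopifnot(nrow(replicates) == length(p_obs))
  A <- cbind(replicates, p_obs)
  const <- apply(A, 2, function(x) max(x) == min(x))
  out <- limma::normalizeQuantiles(A, ties = TRUE)
  if (any(const)) out[, const] <- A[, const]
  list(replicates = out[, seq_len(ncol(replicates)), drop = FALSE],
       p_obs = out[, ncol(A)])
}

#' Empirical bootstrap p-values per pair
#'
#' For each pair, the fraction of bootstrap replicates whose
#' random-collision probability reaches or exceeds the observed propensity,
#' with add-one smoothing: `p = (1 + n_exceed) / (M + 1)`.
#' Small p therefore means the observed contact is stronger than random
#' collision explains.
#'
#' @param replicates Normalized replicate matrix (rows = pairs).
#' @param p_obs Normalized observed values.
#' @param M Number of replicates (defaults to `ncol(replicates)`).
#' @return Numeric vector of p-values in `(0, 1]`; the smallest attainable
#'   value is `1 / (M + 1)`.
#' @export
pair_pvalues <- function(replicates, p_obs, M = ncol(replicates)) {
  stopifnot(M == ncol(replicates))
  (1 + rowSums(replicates >= p_obs)) / (M + 1)
}

#' Benjamini-Hochberg adjustment over a pair map
#'
#' Step-up FDR adjustment over the tested (non-`NA`, upper-triangle)
#' pairs; the output is symmetrized.
#'
#' @param p Symmetric matrix of p-values, `NA` outside the tested family.
#' @return Matrix of q-values with the same `NA` pattern.
#' @export
bh_adjust <- function(p) {
  q <- p
  sel <- upper.tri(p) & !is.na(p)
  q[sel] <- p.adjust(p[sel], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  q
}

new_specific_calls <- function(p, q, specific, family, alpha, M, propensity) {
  structure(list(p_values = p, q_values = q, specific = specific,
                 family = family, alpha = alpha, M = M,
                 n_tested = sum(family[upper.tri(family)]),
                 n_called = sum(specific[upper.tri(specific)]),
                 propensity = propensity, binning = propensity$binning),
            class = "specific_calls")
}

#' Threshold q-values into a specific-interaction call set
#'
#' @param p,q Symmetric p- and q-value matrices (`NA` outside the family).
#' @param alpha FDR threshold (default 0.01).
#' @param propensity The `propensity_map` that was tested; pairs with zero
#'   observed propensity are never called.
#' @param M Number of bootstrap replicates behind `p`.
#' @return An object of class `specific_calls`.
#' @export
call_specific <- function(p, q, alpha = 0.01, propensity, M = NA_integer_) {
  stopifnot(alpha > 0, alpha <= 1)
  family <- !is.na(q)
  # alpha = 1 means "call every tested pair" (q values are capped at 1)
  specific <- family & (q < alpha | alpha >= 1) & propensity$p_obs > 0
  specific[is.na(specific)] <- FALSE
  new_specific_calls(p, q, specific, family, alpha, M, propensity)
}

#' Identify specific Hi-C interactions against the polymer null
#'
#' The main significance pipeline: BLB replicate maps from the null
#' ensemble ([blb_replicates()]), pooled quantile normalization of the
#' replicate maps together with the observed propensities
#' ([quantile_normalize()]), empirical bootstrap p-values
#' ([pair_pvalues()]), Benjamini-Hochberg FDR adjustment, and thresholding
#' at `alpha`. The multiple-testing family is the set of pairs at genomic
#' distance >= 2 bins with nonzero observed propensity and both bins
#' unmasked; adjacent pairs define the propensity normalization and are
#' contacts by construction, so they are never tested.
#'
#' @param propensity A `propensity_map` (see [compute_propensity()]).
#' @param ensemble The null `chain_ensemble` (bin count must match).
#' @param config A [bootstrap_config()].
#' @param alpha FDR threshold (default 0.01).
#' @param d_c Ligation threshold (nm).
#' @return A `specific_calls` object.
#' @export
specific_interactions <- function(propensity, ensemble,
                                  config = bootstrap_config(),
                                  alpha = 0.01,
                                  d_c = ensemble$params$ligation_threshold_nm) {
  n <- nrow(propensity$p_obs)
  stopifnot(n == ensemble$n_beads)
  pairs <- ut_pairs(n)
  fam <- (pairs[, 2] - pairs[, 1]) >= 2 &
    !is.na(propensity$p_obs[pairs]) & propensity$p_obs[pairs] > 0
  reps <- blb_replicates(ensemble, config, d_c)
  M <- ncol(reps)
  norm <- quantile_normalize(reps[fam, , drop = FALSE],
                             propensity$p_obs[pairs][fam])
  pv <- pair_pvalues(norm$replicates, norm$p_obs, M)
  p <- matrix(NA_real_, n, n)
  p[pairs[fam, , drop = FALSE]] <- pv
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q <- bh_adjust(p)
  call_specific(p, q, alpha, propensity, M)
}

#' @export
print.specific_calls <- function(x, ...) {
  cat(sprintf(paste0("<specific_calls> %d of %d tested pairs specific ",
                     "(%.1f%%) at BH-FDR < %g (M = %d)\n"),
              x$n_called, x$n_tested,
              percent_specific(x$n_called, x$n_tested), x$alpha, x$M))
  invisible(x)
}

#' @export
summary.specific_calls <- function(object, ...) {
  d <- abs(row(object$specific) - col(object$specific))
  out <- list(n_tested = object$n_tested, n_called = object$n_called,
              percent = percent_specific(object$n_called, object$n_tested),
              alpha = object$alpha, M = object$M,
              median_distance_bins =
                if (object$n_called > 0)
                  stats::median(d[upper.tri(d) & object$specific])
                else NA_real_)
  class(out) <- "summary.specific_calls"
  out
}

#' @export
print.summary.specific_calls <- function(x, ...) {
  cat(sprintf(paste0("Specific interactions: %d / %d tested (%.1f%%) at ",
                     "BH-FDR < %g\nBootstrap replicates: %d\n",
                     "Median genomic distance of calls: %s bins\n"),
              x$n_called, x$n_tested, x$percent, x$alpha, x$M,
              format(x$median_distance_bins)))
  invisible(x)
}

#' Percentage of contact pairs that are specific
#'
#' @param n_specific Number of pairs called specific.
#' @param n_total Number of pairs tested.
#' @return `100 * n_specific / n_total`.
#' @examples
#' percent_specific(2.28e6, 42.39e6) # ~5.4
#' @export
percent_specific <- function(n_specific, n_total) {
  stopifnot(n_total > 0, n_specific >= 0)
  100 * n_specific / n_total
}

#' Export specific calls as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, propensity, p, q.
#'
#' @param calls A `specific_calls` object.
#' @param path Output path.
#' @export
export_bedpe <- function(calls, path) {
  b <- calls$binning
  idx <- which(calls$specific & upper.tri(calls$specific), arr.ind = TRUE)
  starts <- bin_starts(b)
  df <- data.frame(
    chrom1 = b$chrom, start1 = starts[idx[, 1]],
    end1 = starts[idx[, 1]] + b$resolution,
    chrom2 = b$chrom, start2 = starts[idx[, 2]],
    end2 = starts[idx[, 2]] + b$resolution,
    propensity = calls$propensity$p_obs[idx],
    p = calls$p_values[idx], q = calls$q_values[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Tally specific interactions by chromatin-state pair
#'
#' Labels each called pair by the unordered pair of chromatin states of
#' its two bins (Active, Inactive, Polycomb-repressed, Undetermined) and
#' returns the proportions of each type. Pairs touching an Undetermined or
#' unannotated bin are pooled into `"any-U"`.
#'
#' @param calls A `specific_calls` object.
#' @param states Character vector of per-bin states, values in
#'   `c("A", "I", "P", "U")`; `NA` counts as `"U"`.
#' @return Named numeric vector of proportions over
#'   `A-A, A-I, A-P, I-I, I-P, P-P, any-U`, summing to 1.
#' @export
tally_types <- function(calls, states) {
  n <- nrow(calls$specific)
  stopifnot(length(states) == n)
  states <- as.character(states)
  states[is.na(states) | !states %in% c("A", "I", "P")] <- "U"
  idx <- which(calls$specific & upper.tri(calls$specific), arr.ind = TRUE)
  cats <- c("A-A", "A-I", "A-P", "I-I", "I-P", "P-P", "any-U")
  out <- setNames(numeric(length(cats)), cats)
  if (nrow(idx) == 0) return(out)
  lab <- apply(idx, 1, function(r) {
    s <- sort(c(states[r[1]], states[r[2]]))
    if (any(s == "U")) "any-U" else paste(s, collapse = "-")
  })
  tab <- table(factor(lab, levels = cats))
  out[] <- as.numeric(tab) / nrow(idx)
  out
}
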