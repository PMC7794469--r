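---
title: "From population Hi-C to single-cell chromatin ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From population Hi-C to single-cell chromatin ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Population Hi-C measures, for every pair of genomic bins, how often the two
loci were close enough to be ligated — averaged over millions of cells. Many
of those contacts are not structural signal at all: two loci confined
together in a small nucleus collide at random, and the denser and closer
they are, the more often. chromogrow turns this observation into a complete
modeling pipeline: it builds an explicit physical null model of random
chromatin, tests every Hi-C pair against it, and then uses only the pairs
that survive — the *specific interactions* — to grow large ensembles of
single-cell 3D conformations whose aggregated contact frequencies reproduce
the input map. The ensemble, not a single consensus structure, is the
result: it quantifies cell-to-cell structural heterogeneity, single-cell
TAD-like domains, and many-body contacts that no 2D map exposes.

This vignette explains each model component, the parameters that matter,
the numerical choices, and the limits of what the synthetic test fixtures
can demonstrate.

## The polymer representation

Chromatin is modeled as a tangent-sphere, self-avoiding bead chain:

* one bead per Hi-C bin (2 kb or 5 kb), with a **bead diameter of 25 nm**
  derived from the beads-on-string mass density of 165 bp per 11 nm fiber
  (a 2 kb bin packs ~133 nm of fiber into one bead);
* consecutive bead centers exactly one diameter apart (the simplest bond
  model consistent with "a chain of beads"); non-adjacent centers never
  closer than one diameter (excluded volume);
* all beads inside a **confinement sphere** whose volume is the nuclear
  volume scaled by the fraction of the (ploidy-adjusted) genome being
  modeled: `V = V_nuc * region / genome`, radius `(3V/4π)^(1/3)`. The
  built-in presets are 335 µm³/350 Mb (pre-MBT embryos, diploid),
  524 µm³/350 Mb (post-MBT), and 292 µm³/700 Mb (tetraploid S2R+ cells);
  a 4 Mb region in S2R+ gives a 736 nm sphere and a bead volume fraction
  near 1%;
* two beads are **in contact** when their centers are within the ligation
  threshold `d_c = 80 nm` — the longest distance at which two loci are
  assumed available for Hi-C ligation. Adjacent beads are therefore always
  in contact, which anchors the propensity normalization below.

Confinement applies to bead centers; the one-bead-radius difference this
leaves at the wall is absorbed by the proportional-volume convention. The
25 nm diameter is taken as a constant of the representation rather than
re-derived from the fiber density (a cylinder-equivalent sphere would give
~29 nm); both are configurable in `physical_params()`.

## Hi-C propensities

Raw counts are optionally ICE-balanced (`ice_balance()`; bins with zero or
bottom-2% marginals are masked) and then normalized by the mean count of
adjacent bins:

    p_obs(i, j) = C(i, j) / E_diag(1)

Since neighboring beads always ligate in the physical model, the adjacent
diagonal is the natural unit: propensities are scale-free, the first
off-diagonal averages exactly 1, and `p_obs` can be compared directly with
model contact probabilities. The main diagonal is never used (self-ligation
artifacts), and adjacent pairs are never tested for significance — they
define the normalization and are contacts by construction.

One caveat that the synthetic tests exposed clearly: ICE equalizes
marginals on the assumption that marginal variation is *technical*. On a
matrix whose marginal variation is biological — e.g. a simulated matrix
with TAD blocks and no visibility bias — balancing attenuates genuine
structure (cross-TAD loop propensities shrank several-fold in our
fixtures). Balance real data; do not balance bias-free simulations.

## The null ensemble: sequential growth with resampling

The null model is a weighted ensemble of random, self-avoiding, confined
chains — chromatin as geometry alone would have it. Chains are grown by
sequential importance sampling:

1. bead 1 uniform in the confinement sphere;
2. for bead *t*, sample `K = 32` uniform directions on the bond sphere,
   discard trials that collide or leave the sphere, pick uniformly among
   the valid ones, and multiply the chain's weight by the Rosenbluth
   factor `n_valid / K`;
3. the weighted ensemble then targets the uniform distribution over all
   geometrically realizable chains in the volume.

Weights of confined chains are heavy-tailed — a chain hugging the wall
loses nearly half its trial directions at every step — so long chains
degenerate without intervention. At **checkpoint lengths** (default every
`⌈n/20⌉` beads) the population's effective sample size
`ESS = (Σw)²/Σw²` is monitored; when it falls below half the population,
chains are resampled systematically in proportion to their weights and
weights are reset (total preserved, ESS returns to N). Chains that die
(no valid trial) carry zero weight and are replaced at the next
checkpoint. Everything is reproducible bit-for-bit from one master seed:
all randomness, including inside the compiled grower, flows from R's RNG.

`contact_probability()` aggregates the ensemble into the null map

    p_null(i, j) = Σ_k I_k(i, j) w_k / Σ_k w_k ,

with `I_k = 1` when beads i, j of chain k are within `d_c`.

Collision checks use a direct scan over the partial chain. A spatial hash
would make each check O(1), but at the population sizes grown here
(10³–10⁵ replicas advancing in lockstep for checkpoint resampling) the
per-chain hash tables cost more memory than the scan costs time, and the
scan is branch-light; the dense scan is the deliberate choice.

A note on precision: because resampling duplicates lineages, the effective
number of *independent* chains for early-bead contact pairs is set by the
surviving founder count, not by N. Two independent 10⁴-chain runs of a
50-bead system agree entrywise to ~0.05, not the ~0.02 naive binomial
arithmetic would suggest; ensemble-level comparisons in the tests are
sized accordingly.

## Specific interactions: BLB bootstrap against the null

Each tested pair (genomic distance ≥ 2 bins, nonzero observed propensity,
both bins unmasked) receives an empirical p-value against the null:

* **Bag of Little Bootstraps.** `s` subsets of `b` chains (defaults
  `s = 4`, `b` ≈ 1300 or ≤ 1% of the ensemble) are drawn without
  replacement; each subset is resampled multinomially up to the full
  ensemble size, the counts acting as weights, for `M` total replicate
  `p_null` maps (production default `M = 5000`).
* **Pooled quantile normalization** maps the ranks of every replicate map
  and of the observed propensities onto the mean sorted vector across all
  of them, putting observed and null values on one scale while preserving
  ranks exactly.
* **Empirical p-values with add-one smoothing**:
  `p = (1 + #{replicates ≥ observed}) / (M + 1)`, so small p means the
  contact exceeds what random collision explains and p is never zero.
* **Benjamini–Hochberg** adjustment over the tested family; pairs with
  `q < 0.01` are the specific interactions.

The smallest attainable q is `(m / n_floor) / (M + 1)` when `n_floor`
pairs tie at the p-value floor; with few replicates this can put an entire
call set on a knife edge just above the threshold, so M should be chosen
with the family size in mind (the desk-scale fixtures use M = 1000 for
~4,850 tested pairs; the production default M = 5000 is comfortable).

## The constrained ensemble

To rebuild 3D structure from the calls, the same grower is tilted by the
selected targets `q_target = min(p_obs, 1)` (clipped because a contact
probability is a proportion of chains). When bead *t* is placed, each
valid trial position x is additionally weighted by a per-pair Bernoulli
factor over the earlier beads j that share a target with t:

    b_jt * q_jt          if dist(x_j, x) < d_c
    1 − min(1, b_jt*q_jt) otherwise

The trial is chosen proportionally to this likelihood, and the importance
weight tracks the proposal/target ratio, so the weighted ensemble targets
the geometric prior tilted by the product of per-pair contact likelihoods
— a contact-level realization of scoring partial ensembles by the
likelihood of the observed frequencies. With an empty target map the
factors are all 1 and the constrained grower *is* the null grower, down to
identical chains for identical seeds. Effective probabilities are capped
at 0.995 so no single pair becomes a hard constraint that kills chains.

**Calibration.** The bias factors `b` start at 1 and are fitted by an
iterative proportional-fitting loop: grow a batch, aggregate its map, and
update `b ← b * clip((q_target / p_sim)^0.5, 1/2, 2)` on target pairs
(a vanished pair gets the maximal boost). Three numerical choices matter,
all learned from watching the raw dynamics:

* the square-root damping and the modest clip (`kappa = 2`): each target
  pair tilts every later growth step, so the collective response to a
  joint update is sublinear and undamped full-ratio updates overshoot —
  the target correlation collapsed from 0.91 to ~0.3 within a few rounds
  when updated at full strength;
* a clamp on the cumulative bias (`bias_max = 4`): pairs the geometry
  cannot satisfy would otherwise accumulate ratio > 1 forever and
  destabilize the whole population;
* best-state selection: every round's batch map is scored against the
  target and the best state seen is returned, so the reported history is
  non-decreasing and a late divergent round cannot spoil the fit.

`simulate_contact_map()` aggregates any ensemble back into a map;
`map_correlation()` compares maps by plain Pearson r over pairs i < j and
by the stratum-adjusted correlation r′ (per-|i−j| Pearson correlations
combined with weights proportional to stratum size times the product of
stratum standard deviations), which removes the r-inflation that the
shared distance decay produces. On the synthetic recovery fixture the
constrained ensemble reaches r ≈ 0.97 and r′ ≈ 0.78 against its target
map on the target support (the spec of this comparison: r is computed on
the pairs the model was asked to realize; including never-targeted pairs,
where the target is 0 by construction but any polymer has residual decay
contact, anti-correlates within strata and measures the support choice,
not the fit).

## Single-cell structure analytics

Each chain of an ensemble is a model single-cell conformation; analytics
operate on its spatial-distance map.

* **Compactness**: radius of gyration and end-to-end distance.
* **Clustering**: Ward (`ward.D2`) hierarchical clustering on vectorized
  upper-triangle distance maps, clusters relabeled 1..k by increasing
  weighted mean R_g; per-cluster aggregated contact maps
  proportion-weight back to the full-ensemble map exactly.
* **Boundary strength** at position i: the mean distance between the w
  bins before i and the w bins from i, divided by the average of the two
  within-window mean distances (w defaults to 10 bins; ends padded with
  1; summed-area tables make the curve O(n)). Single-cell boundaries are
  local maxima ≥ 2.2, kept greedily in decreasing strength with a minimum
  separation of w.
* **TAD-like domains**: each interval between adjacent boundaries (region
  ends count as flanks) is accepted when its internal distances are
  smaller than its distances to equal-width flanks by a one-sided
  Wilcoxon rank-sum test, BH-adjusted within the conformation at 0.05.
  A conformation without internal boundaries contributes zero domains;
  intervals under 3 bins are untestable and skipped.
* **Boundary probability**: conformations sampled with replacement in
  proportion to their weights; per-bin boundary frequencies, the
  histogram of per-conformation domain counts, and the fraction with at
  least one domain. `peak_enrichment()` averages any per-bin profile
  around peak centers (strandless) relative to the regional mean;
  `virtual_4c()` extracts anchor rows; `multibody_fraction()` reports the
  weighted fraction of conformations with all pairwise locus distances
  within `d_c`, optionally conditioned on a sub-pair contact, and reduces
  exactly to the simulated contact map for a single pair of bins.

## Synthetic fixtures: what they do and do not show

`generate_toy_hic()` emulates the statistical structure the pipeline
consumes — power-law (default exponent −1) or externally supplied distance
decay, multiplicative TAD blocks, implanted loops, negative-binomial
counts (dispersion 0.1 by default, typical of overdispersed Hi-C) — with
labeled ground truth. Two lessons from building the recovery fixture are
worth recording. First, a pure power-law background is *not* realizable
by any confined chain ensemble: at short range it demands contact
probabilities several-fold below what chain geometry forces, so a model
ensemble can never track it stratum-by-stratum. A coherent fixture
follows the generative premise of the method itself — polymer background
times specific enrichments — which is what passing `decay_profile` the
null ensemble's own decay produces. Second, at realistic steep decay a
"5× enriched" far loop at shallow sequencing has an expected count of a
few reads; its negative-binomial draw lands at the null level often
enough that the planted truth is simply false in that realization. The
recovery fixture therefore uses deep counts (1000 expected at distance 1)
and conspicuous 12× loops.

`generate_labeled_conformations()` grows all structural fixtures with the
package's own sampler so they satisfy every physical invariant:
globule-pairs (two 25%-packing globules bridged by a short guided linker
across a 60 nm gap; the mid-linker position is the planted boundary,
grown one small independent population per conformation so fixtures are
mutually independent), unstructured coils at the ~1% packing of a real
nuclear region, and compact/extended mixtures (30% vs 2% packing) for
clustering.

What the fixtures do **not** show: real Hi-C visibility biases (the toy is
bias-free, hence unbalanced), inter-chromosomal context, chromatin-state-
dependent fiber properties, and any loop-extrusion dynamics — the model
is deliberately minimal, with geometry and the input map as its only
ingredients.

A genuine scientific caveat belongs here rather than in any test: random
confined self-avoiding chains *do* contain TAD-like domains. Across
packing fractions 0.0005–0.01 the boundary/domain pipeline finds on the
order of 1–2 significant domains per unstructured coil, while bead-order-
shuffled distance maps (which destroy all spatial autocorrelation) yield
exactly zero. Confinement plus chain connectivity alone creates transient
domain-like structure — the same reason a majority of modeled single-cell
conformations carry TAD-like domains even where the population map shows
no TADs. A permutation null is therefore a floor, not a calibration
target, for single-cell domain counts.

## Problem sizes and determinism

Production-scale defaults follow the method's normal operating point:
2×10⁵ null chains, M = 5000 bootstrap replicates, 5×10⁴ constrained
conformations, 5,000 conformations sampled for boundary statistics. The
test-suite and acceptance-script runs use desk-scale versions chosen so
that every stochastic check keeps a comfortable margin at its tolerance:
100-bin maps, 4×10³-chain nulls, M = 500–1000, 5×10³-chain constrained
ensembles, 1.2×10⁵-chain pairs for the null-reduction comparison, and a
10⁵-chain rejection-sampling oracle. Every run — including the compiled
grower — draws exclusively from R's RNG, so a single seed reproduces any
result bit-for-bit.

## Known limitations

* The Bernoulli-factor tilt realizes pairwise targets; it does not impose
  higher-order constraints, and strongly conflicting targets saturate at
  the bias clamp rather than being satisfied.
* Importance-weight degeneracy limits the independent information in very
  long confined chains; checkpoint resampling controls it but duplicated
  lineages reduce effective precision for short-range pairs.
* ICE masking uses a simple marginal quantile; pathological bins beyond
  low coverage are not detected.
* The boundary-strength statistic is scale-dependent through w; the 2.2
  threshold is meaningful for windows comparable to TAD size at 2 kb
  resolution and should be re-examined for other resolutions.
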