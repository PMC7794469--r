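# chromogrow

Single-cell 3D chromatin ensembles from population Hi-C.

Population Hi-C reports, for every pair of genomic bins *i, j*, a contact
count *C(i, j)* averaged over millions of cells — but much of that signal
is random collision of a polymer confined in a small nucleus, and none of
it directly reveals what any single cell looks like. chromogrow implements
a complete, physically grounded route from a binned contact map to large
ensembles of single-cell 3D conformations:

1. **A physical null model.** Random, self-avoiding bead chains
   (25 nm beads, one per 2 kb or 5 kb bin, 165 bp/11 nm fiber density)
   are grown inside a sphere whose volume is the nuclear volume scaled by
   the modeled genome fraction. Growth is sequential importance sampling
   with Rosenbluth weights and checkpoint resampling; the weighted
   ensemble targets the uniform distribution over all geometrically
   realizable confined chains. Contacts are pairs within the ligation
   threshold d_c = 80 nm, giving the random-collision map
   *p*<sub>null</sub>(i, j) = Σ<sub>k</sub> I<sub>k</sub>(i, j) w<sub>k</sub> / Σ<sub>k</sub> w<sub>k</sub>.
2. **Specific interactions.** Observed propensities
   *p*<sub>obs</sub>(i, j) = C(i, j) / E<sub>diag</sub>(1) (counts
   normalized by the mean adjacent-bin count) are tested against the null
   with a Bag-of-Little-Bootstraps scheme: M replicate null maps, pooled
   quantile normalization, empirical p-values
   p = (1 + #{p<sub>null</sub> ≥ p<sub>obs</sub>}) / (M + 1), and
   Benjamini–Hochberg control at FDR 0.01.
3. **Hi-C-concordant ensembles.** The same grower, tilted per pair by
   calibrated Bernoulli likelihood factors toward the selected target
   probabilities, generates tens of thousands of conformations whose
   aggregated contact map matches the input.
4. **Single-cell analytics.** Distance maps, radius of gyration,
   Ward clustering of conformations, boundary-strength profiles
   (threshold 2.2) with rank-sum-tested TAD-like domains at FDR 0.05,
   boundary-probability tracks and their enrichment at protein binding
   peaks, virtual 4C, and many-body contact fractions.

A synthetic-data module generates Hi-C matrices (distance decay, TAD
blocks, loops, negative-binomial noise) and labeled conformation fixtures
with known ground truth, so the entire pipeline is testable without any
download.

## Worked example

Identify specific interactions in a synthetic 200 kb region (100 bins at
2 kb) and rebuild its single-cell ensemble:

```r
library(chromogrow)

## physical model for a 200 kb region in S2R+ cells
params <- physical_params(resolution_bp = 2000, nuclear_volume_um3 = 292,
                          genome_size_mb = 700, region_length_mb = 0.2)
params
#> <physical_params> 2000 bp/bead, bead 25 nm, d_c 80 nm, confinement radius 271.1 nm

## null ensemble of random confined chains
null_ens <- build_null_ensemble(growth_config(100, 4000, master_seed = 7), params)
null_ens
#> <chain_ensemble> null: 3992 chains x 100 beads, ESS 1673

## synthetic Hi-C: polymer-decay background + 3 TADs + 3 loops
p0 <- simulate_contact_map(null_ens)
dd <- abs(row(p0) - col(p0))
profile <- vapply(1:99, function(s) mean(p0[dd == s]), numeric(1))
toy <- generate_toy_hic(100,
                        tads = list(c(10, 40, 3), c(45, 70, 3), c(75, 95, 3)),
                        loops = list(c(20, 80, 12), c(15, 60, 12), c(50, 90, 12)),
                        seed = 5, decay_profile = profile, base_count = 1000)

## propensities and bootstrap significance against the null
prop <- compute_propensity(toy$matrix)
calls <- specific_interactions(prop, null_ens,
                               bootstrap_config(1000, 400, 4, seed = 21))
summary(calls)
#> Specific interactions: 918 / 4849 tested (18.9%) at BH-FDR < 0.01
#> Bootstrap replicates: 1000
#> Median genomic distance of calls: 13 bins

## constrained 3D ensemble from the specific interactions
tgt <- select_targets(prop, calls, "specific")
cal <- calibrate(tgt, params, growth_config(100, 1000, master_seed = 31))
ens3d <- grow_constrained_ensemble(tgt, params,
                                   growth_config(100, 5000, master_seed = 77),
                                   cal)
psim <- simulate_contact_map(ens3d)
sup <- tgt$q > 0
sprintf("r = %.2f, r' = %.2f against the target map",
        map_correlation(psim, tgt$q, mask = sup),
        map_correlation(psim, tgt$q, "distance_adjusted", mask = sup))
#> "r = 0.97, r' = 0.79 against the target map"

## single-cell TAD-like domain content
boundary_probability(ens3d, sample_size = 1000, seed = 11)
#> <boundary_probability> 1000 conformations sampled; 100.0% with >= 1 TAD-like domain
```

All 918 called pairs carry the planted structure: the three implanted
loops are recovered, the aggregated map of the reconstructed ensemble
correlates with its target at r = 0.97 (r′ = 0.79 after removing
distance-decay inflation), and every sampled conformation carries the
planted TAD-like domains. Every step is bit-reproducible from the seeds
shown. `export_bedpe()`, `write_bedgraph()`, and `write_xyz()` export
calls, per-bin tracks, and conformations for genome browsers and
molecular viewers; `vignettes/chromogrow-methods.Rmd` documents the
models, parameters, and numerical choices in full.

A thin command-line wrapper over the same functions is included at
`inst/scripts/chromogrow.R` (subcommands `simulate`, `null`, `call`).

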