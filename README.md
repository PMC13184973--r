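# biofilmgeo

Small-scale biogeography analysis of biofilm microbial communities.

Biofilms in a single connected environment — a shower hose, a pipe wall, a
reactor coupon — harbour taxa arranged in gradients and patches at
centimetre to micrometre scales. Any sequencing-based study averages over
whatever area one sample covers, so the sampling strategy itself shapes the
diversity, co-occurrence and scaling-law estimates a study reports.
`biofilmgeo` is an R package for researchers who profile biofilms with
spatially indexed amplicon count tables (taxa × sections, plus per-section
positions, areas, cell densities and thicknesses) and want to quantify that
spatial structure and its consequences.

## What it computes

**Neighbourhood diversity.** The expected number of cells in a planar patch
of area *A* is ρ·*A* (ρ in cells/cm²); in a spherical neighbourhood of
radius *r* within a biofilm of thickness *t*, the sphere–slab intersection
volume 2π(r²a − a³/3), a = min(r, t/2), times the volumetric density ρ/t.
The expected number of distinct taxa among *n* cells drawn from relative
abundances *p₁…p_m* is the Heaps'-law expectation

    E[R_m(n)] = m − Σᵢ (1 − pᵢ)ⁿ

evaluated at real-valued *n* (`heaps_expected_richness()`), with a
Monte-Carlo multinomial cross-check (`mc_neighborhood_richness()`).

**Spatial structure.** Per-taxon monotonic trends (Spearman, exact
permutation p for short series) and nonrandom arrangements (Wald–Wolfowitz
runs test, exact runs distribution), BH-corrected (`classify_trends()`);
core/satellite partitioning from ranked abundance–occupancy
(`core_satellite_partition()`); distance-decay tables of Bray–Curtis
dissimilarity versus axial distance (`distance_decay()`), and slope-change
(breakpoint) detection by continuous two-segment least squares with
bootstrap standard errors (`breakpoint_fit()`).

**Sampling-strategy simulation.** Side merging, contiguous and
discontiguous pooling of sections into larger samples, rarefaction back to
the original depth, and sweeps quantifying how sample area distorts alpha
diversity, beta dispersion and the number of significantly co-occurring
taxon pairs under an exact hypergeometric presence/absence test
(`apply_plan()`, `strategy_sweep()`, `equalized_sweep()`, `pair_pvalue()`).

**Species–area scaling laws.** Exact and randomised species accumulation
curves (`sar_exact()`, `sar_random()`) and nonlinear fits of the power law
R = c·Aᶻ and the logarithmic power law R = [b + c·log A]ᶻ, where z is the
spatial turnover exponent, with RMSE model comparison
(`fit_scaling_law()`, `compare_laws()`, `turnover_vs_samplesize()`).

**Synthetic communities.** `generate_biofilm()` simulates spatially
structured count tables with known truth — Zipf or lognormal base
abundances, planted monotonic/peaked taxa, Dirichlet section noise, fixed
sequencing depth — with `environment_preset("controlled")` and
`environment_preset("uncontrolled")` encoding a homogeneous and a
heterogeneous study environment.

## Worked example

```r
library(biofilmgeo)

# a heterogeneous synthetic environment: 120 sections x 4000 reads
sim <- generate_biofilm(environment_preset("uncontrolled",
                                           n_sections = 120, depth = 4000,
                                           seed = 1))

# how many taxa share a 10 um^2 patch or a 5 um-radius neighbourhood?
prof <- neighborhood_richness_profile(sim$counts, sim$physical,
                                      areas_um2 = c(10, 1e6), radii_um = 5)
aggregate(cbind(expected_cells, expected_richness) ~ query, prof, median)
#>          query expected_cells expected_richness
#> 1      area_10   1.668388e+00          1.243904
#> 2 area_1000000   1.668388e+05         66.500000
#> 3     radius_5   1.478570e+00          1.232571

# which scaling law describes richness accrual here?
cmp <- compare_laws(sim$counts, sim$metadata, n_sar = 50, seed = 2)
cmp$win_fraction_lpl
#> [1] 1
median(cmp$results$rmse_pl); median(cmp$results$rmse_lpl)
#> [1] 12.53898
#> [1] 3.618476
```

A 10 µm² patch is expected to hold fewer than two cells — and so at most
one or two taxa — despite hundreds of taxa in the full section: local
neighbourhoods are far poorer than section-level richness suggests. On
this heterogeneous environment the logarithmic power law out-fits the
power law on all 50 randomised species-accumulation curves (median RMSE
3.6 vs 12.5 taxa); on the `"controlled"` preset the ordering reverses.

The full pipeline (simulate → diversity → trends → neighbourhoods →
resampling → co-occurrence → scaling laws → breakpoints) runs from one
config and writes tidy TSVs plus a digest manifest:

```r
run_pipeline(list(seed = 1, preset = "uncontrolled"), "out/")
```

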