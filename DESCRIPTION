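Package: biofilmgeo
Title: Small-Scale Biogeography Analysis of Biofilm Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify centimetre- to micrometre-scale spatial
    structure in biofilm microbial communities profiled by amplicon
    sequencing. Estimates the expected number of cells and distinct taxa in
    local planar and spherical neighbourhoods from areal cell densities via
    a Heaps'-law expectation, detects per-taxon spatial trends (Spearman
    monotonic trends and Wald-Wolfowitz runs tests with Benjamini-Hochberg
    correction), partitions communities into core and satellite members
    from abundance-occupancy rankings, locates slope changes in
    distance-decay relationships by segmented least squares with bootstrap
    errors, simulates alternative sampling strategies (side merging,
    contiguous and discontiguous pooling with rarefaction) and measures
    their distortion of alpha diversity, Bray-Curtis beta diversity and
    presence-absence co-occurrence counts, and fits power-law and
    logarithmic power-law species-area relationships to species
    accumulation curves. Includes a synthetic spatially structured
    community generator for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
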