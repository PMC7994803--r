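Package: rhodochron
Title: Chronology of Serial Red-Plastid Endosymbioses from Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether serial endosymbiosis scenarios for the
    spread of red algal-derived plastids are chronologically possible.
    Computes feasibility windows for plastid transfers by intersecting 95%
    highest-posterior-density (HPD) age intervals of donor and recipient stem
    lineages under explicit transfer scenarios, summarizes MCMC posterior
    traces and dated trees (HPD intervals, median ages, cross-analysis
    comparisons, clock-likeness ranking), constructs fossil-calibration prior
    densities (soft-bound uniform, skew-normal with solved scale, truncated
    Cauchy), screens single-gene bootstrap trees for endosymbiotic gene
    transfer via sister-group frequencies, strips compositionally
    heterogeneous alignment sites, and simulates all required inputs
    (birth-death chronograms, relaxed-clock branch rates, posterior traces,
    gene trees with implanted transfers, compositionally biased alignments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
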