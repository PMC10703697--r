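Package: ashmscan
Title: Aberrant Somatic Hypermutation Scanning in Paired Lymphoma Genomes
Version: 0.1.0
Authors@R:
    person("Genomics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling aberrant somatic hypermutation (aSHM) during
    follicular lymphoma (FL) to double-hit lymphoma (DHL) transformation in
    paired longitudinal genomes. Implements a somatic-variant post-filter
    cascade with a rejection ledger, ROSE-style super-enhancer calling from
    H3K27ac peaks, histone-mark region partitioning, TAD and A/B-compartment
    annotation, anchored mutation-density profiles, rainfall/kataegis
    detection, a fixed-width differential segment scan with binomial testing
    and FDR control, TAD-resident gene-pair enhancer-retargeting prediction
    via rank aggregation, exact 2x2 and signed-rank statistics, and a fully
    seeded synthetic paired-cohort generator so every stage is testable
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
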