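Package: HiCdegron
Title: Contact-Map Analytics for Acute-Depletion Hi-C Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how chromatin architecture responds to acute protein
    depletion from Hi-C style contact maps. Provides pair-level filtering and
    binning into per-chromosome contact matrices, sequencing-depth matching,
    ICE iterative-correction balancing, distance-decay expected profiles and
    observed/expected transforms; A/B compartment eigenvectors and saddle-plot
    compartmentalization strength; insulation scores, boundary meta-profiles,
    rescaled meta-domain pile-ups and intra-domain enrichment; pair-anchored
    aggregate analyses (PE-SCAn around binding-hotspot pairs, loop APA,
    stratified promoter-pair pile-ups, stripe decay curves); loop
    classification by ChIP occupancy, ROSE-style hotspot stitching and
    percent-change statistics between conditions. A synthetic contact-map
    generator with known ground truth (power-law decay, compartment
    checkerboard, domains, focal loops, stripes, clustered hotspots, and
    per-feature perturbation factors) supports parameter-recovery testing and
    in-silico depletion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
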