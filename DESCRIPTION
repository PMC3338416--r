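Package: diviss
Title: Differential In Vitro and In Silico Screening for Cancer Target
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chemocentric cancer target
    identification by differential screening. Covers single-point
    cytotoxicity screening quality control (Z' factor, signal-to-background,
    hit calling), dose-response IC50 fitting with censoring and
    tumor/normal selectivity classification, Bemis-Murcko chemotype
    clustering with enrichment-guided library expansion, ligand-based
    virtual target profiling using pharmacophore feature-pair descriptors
    with inverse-distance-weighted affinity interpolation inside an
    applicability domain, and differential target-set analytics (Venn
    partitions, protein family composition, oncogene-score prioritization,
    drug polypharmacology ranking, pathway overlap counts). Includes a
    synthetic campaign generator with exported ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
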