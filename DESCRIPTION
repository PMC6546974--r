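Package: mima
Title: Multi-Region Immune and Mutational Analysis of Metastatic Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lineage classification of somatic mutations and T-cell receptor
    (TCR) clonotypes across multiple metastases of the same patient,
    mutational-signature refitting by non-negative least squares with
    attribution thresholds and residual/entropy diagnostics, a
    simulation-based immunoediting (neo-epitope depletion) test that
    preserves trinucleotide context, TCR repertoire clonality, overlap and
    tree-concordance statistics, and tumor-microenvironment scores
    (cytolytic activity, immunophenogram/IPS, k-nearest-neighbour cell
    density).  A seeded synthetic multi-metastasis cohort generator provides
    ground-truth data with the statistical structure every downstream stage
    assumes, so the full pipeline is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    vegan,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    igraph,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
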