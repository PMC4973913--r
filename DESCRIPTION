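Package: surfaceome
Title: Label-Free Quantification and Cell-Surface Proteome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for label-free shotgun proteomics of cell-surface
    (surfaceome) samples. Reads MaxQuant proteinGroups tables, computes
    label-free quantification indices (emPAI, NSAF, iBAQ) with abundance
    classes, counts theoretically observable tryptic peptides under
    length, charge, hydrophobicity and retention-time constraints,
    performs Fisher's-exact gene-ontology enrichment over intensity-ranked
    protein bins with two-sample profile comparison, classifies proteins
    as cell-surface by a Boolean gene-ontology expression, and runs a
    permutation-based moderated t-test (SAM-style, with slope s0 and
    left-censored normal imputation) for differential analysis. Includes
    seeded synthetic-data generators reproducing dilution-series and
    UPS1-in-yeast spike-in benchmark designs together with accuracy
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
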