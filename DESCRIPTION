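Package: mockasv
Title: Mock-Community Calibrated ASV Filtering and Community Structure
    for Protist Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of denoised 18S V9 amplicon sequence
    variant (ASV) tables from benthic protist metabarcoding surveys.
    Implements per-library read-proportion threshold calibration from
    co-sequenced mock communities, partitioning of environmental count
    tables into main, strictly filtered and low-abundance datasets,
    identity-based taxonomic assignment by unit-cost global pairwise
    alignment against a PR2-style reference database, exact genotype
    search, alpha diversity and analytic rarefaction, presence/absence
    beta diversity (Jaccard, non-metric multidimensional scaling,
    one-factor, pairwise and two-factor nested PermANOVA with
    permutation p-values), and unique/shared ASV set partitioning
    across depth and island groupings. A synthetic-data module
    generates mock libraries and island-by-depth environmental
    datasets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
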