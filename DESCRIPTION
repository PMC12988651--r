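Package: genebankr
Title: Genotype-Based Curation and Diversity Analysis of Genebank Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-based curation of crop genebank collections:
    SNP genotype quality control, minor-allele-frequency filtering and linkage
    pruning; pairwise relatedness (Nei standard genetic distance, VanRaden
    genomic relationship matrix, identity-by-state and method-of-moments
    genome-wide identity-by-descent); multi-criteria duplicate-accession
    detection with passport name confirmation and retention resolution;
    ancestry estimation by nonnegative matrix factorisation with masked
    cross-entropy and Evanno delta-K model selection; per-group diversity
    statistics, Weir-Cockerham F-statistics and one-level AMOVA; and
    rarefaction-based geographic enrichment testing.  A synthetic-panel
    generator with planted duplicates, relatives and admixture provides
    ground truth for validation, and numbered analysis scripts run the whole
    workflow end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
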