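Package: hkgselect
Title: Reference Gene Selection for Hypoxia Studies from RNA-seq Screens and qRT-PCR Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage selection of housekeeping (reference) genes for
    relative gene expression studies under a two-condition contrast such as
    hypoxia versus normoxia. Stage one screens candidate genes in bulk
    RNA-seq count data by coefficient of variation under TPM and
    median-of-ratios normalization combined with log2 fold change into a
    summed arbitrary score and rank. Stage two validates shortlisted
    candidates from qRT-PCR Ct tables with six established stability and
    quantification methods (GeNorm, NormFinder, BestKeeper, comparative
    delta-Ct, RefFinder rank aggregation, and Livak 2^-ddCt relative
    quantification) and combines them into per-cell-line and overall
    stability rankings. Includes a negative-binomial count and Ct-table
    simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
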