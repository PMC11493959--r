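Package: delfitf
Title: Tumor Fraction Estimation from Cell-Free DNA Fragmentation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates circulating tumor fraction from low-coverage whole-genome
    sequencing of cell-free DNA without requiring tumor mutations. Fragment
    coordinates are tallied into a reference tiling of 100-kb autosomal bins,
    GC-corrected short/long fragment ratios are summarized over 5-Mb regions,
    chromosome-arm aneuploidy z-scores and a plasma aneuploidy score are
    computed, and the genome-wide fragment-length distribution is summarized by
    a 12-component normal mixture. A random-forest regressor maps these 16
    features to a predicted mutant allele frequency (the DELFI-TF score) with
    leave-one-patient-out cross-validation, and longitudinal series of scores
    are reduced to per-patient slopes with eligibility windows around disease
    progression. A synthetic-cohort simulator with known ground-truth tumor
    fractions makes the whole pipeline testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    data.table,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
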