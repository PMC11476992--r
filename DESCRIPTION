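Package: swathdep
Title: Label-Free SWATH-MS Differential Expression with Bilateral
    Concordance Filtering and Targeted MRM Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for data-independent acquisition
    (SWATH-MS) proteomics of paired-eye (OD/OS) vitreous samples across
    developmental timepoints. Provides readers and writers for long-format
    transition quant tables and ion libraries, most-likely-ratio (MLR)
    normalization of protein area matrices, transition-to-peptide-to-protein
    intensity roll-up with top-k selection and peptide-confidence filtering,
    a bilateral-concordance fold-change filter for differential expression
    with cross-timepoint intersection and z-score summarization, a targeted
    MRM(HR) validation stage with signal-to-noise filtering, housekeeping
    normalization and unpaired t-tests, ion-library merge and overlap
    accounting, and a seeded synthetic-data generator with ground truth for
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
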