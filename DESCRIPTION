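Package: msclone
Title: Clonality Inference and Mutational Signature Analysis for Multiple
    Synchronous Lung Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines whether multiple synchronous lung tumours from one
    patient are independent primary tumours or clonally related (primary and
    metastasis) from their somatic variant profiles. Implements post-caller
    somatic variant filtering (SNV, indel and structural-variant rule sets),
    shared-mutation clonality inference with hotspot-aware classification and
    cohort-comparison Fisher tests, six-class and 96-class trinucleotide
    mutation spectra, APOBEC TCW-motif enrichment with its exact significance
    test, and copy-number correlation clonality against an inter-patient
    background distribution. Ships a synthetic multi-tumour cohort generator
    with known ground-truth clonal relationships so the full pipeline is
    testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
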