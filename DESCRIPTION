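Package: pdxresist
Title: Classification of Chemoresistance-Linked Somatic Mutations in
    Iteratively Treated Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and classify somatic mutations associated
    with adaptation to chemotherapy in serially treated patient-derived
    xenografts (PDXs). Implements read-count based somatic mutation
    calling thresholds, per-treatment-arm classification of mutations as
    de novo, completely depleted, enriched, partially depleted or
    unchanged (Fisher exact test on allele counts with false discovery
    rate control and a minimum allele-frequency shift), consensus
    deleteriousness labelling from SIFT/PolyPhen-2 style predictions,
    two-by-two Fisher pathway over-representation, a random-gene-set null
    for expression-drug IC50 correlation enrichment, and a deep-amplicon
    per-base error model with detection-limit calls. Includes seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
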