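Package: famvar
Title: Family-Based Rare-Variant Association Testing for Healthy-Aging Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for candidate-gene sequencing studies in extended
    pedigrees: pedigree kinship computation, Mendelian-inconsistency
    detection and minor-allele-frequency-stratified variant filtering,
    derived healthy-aging phenotypes (Healthy Aging Index, telomere length
    from T/S ratio, Friedewald LDL), life-table trait exceptionality
    scores, kinship-adjusted single-variant linear mixed models, and
    family-based rare-variant burden and kernel tests (unweighted and
    frequency-weighted sum scores, an adaptive permutation-weighted sum
    test, and a famSKAT-style kernel test). Includes a synthetic-data
    generator producing three-generation pedigrees, gene-dropped rare
    variants, polygenic phenotypes and Gompertz life tables with known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
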