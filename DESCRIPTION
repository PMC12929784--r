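Package: rnaconcord
Title: DNA-RNA Alteration Concordance Screening and Tumor Transcriptional
    Burden Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating tumor DNA and RNA profiling reports at the
    call level: detection of same-gene concordant alteration events, an
    exhaustive DNA-gene by RNA-gene association screen using Fisher's exact
    test with Benjamini-Hochberg false discovery control, pathway
    over-representation and transcription-factor/target annotation of
    significant gene pairs, and survival analysis stratified by tumor
    transcriptional burden (the per-patient count of genes with altered
    expression). Includes a seeded synthetic-cohort generator that emulates
    the statistical structure of paired clinical DNA/RNA profiling so the
    whole pipeline can be exercised and calibrated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
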