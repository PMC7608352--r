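Package: cnvcohort
Title: CNV Case-Control Association Pipeline for Biobank-Style Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for testing association between a
    recurrent copy-number deletion and clinically coded phenotypes in a
    biobank-style cohort, built around the 15q11.2 BP1-BP2 microdeletion
    and congenital cardiovascular malformation (CVM). Provides PennCNV
    rawcnv parsing, per-sample CNV quality control (waviness factor and
    genome-wide call count), interval-overlap genotyping of the deletion
    locus, a deterministic codebook-driven ICD-9/ICD-10/OPCS-4 phenotyping
    cascade (including patent foramen ovale and bicuspid aortic valve
    disambiguation rules), a statistical battery (Woolf odds-ratio
    confidence intervals, Yates-corrected chi-squared, covariate-adjusted
    linear/Poisson/logistic/multinomial regression, sex-stratified
    fecundity models), and a fully parameterised synthetic cohort
    generator with ground-truth labels so the whole pipeline is testable
    without access-controlled data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    IRanges
Config/testthat/edition: 3
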