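Package: mosaicfrac
Title: Detection and Quantification of Postzygotic Mosaic Variants from
    Deep Sequencing and Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as a tested analysis pipeline, a mosaicism
    study workflow for a Rett-syndrome cohort: Bayesian screening of deep
    panel-sequencing read counts for postzygotic (mosaic) variants,
    ultra-deep amplicon validation with hierarchical Bayesian mutant
    allele fraction (MAF) estimation, droplet digital PCR quantification
    with exact binomial confidence intervals and a simulated limit of
    detection, and cohort-level exact contingency statistics (two-sided
    Fisher test, conditional-MLE odds ratio with exact bounds). A
    synthetic-data generator emulates all study inputs (finite template
    copies, sequencing error, Poisson droplet loading, sex-stratified
    cohort rates, multi-tissue MAF panels) so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
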