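Package: pidscreen
Title: Microarray-Based Genetic Screening for Primary Immunodeficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for customized SNP-array genetic
    screening of primary immunodeficiency disorders (PID). Implements
    cluster-based genotype calling from two-channel probe intensities with a
    zCall-style recalling step for rare variants, a quality-control cascade
    (probe and sample call-rate filters, exact Hardy-Weinberg testing, sex
    inference), a pathogenic-SNV filter cascade (pathogenicity class,
    population frequency, cohort recurrence, male X-heterozygote removal,
    cluster-quality review), copy-number and long-contiguous-stretch-of-
    homozygosity (LCSH) detection from log-R-ratio and B-allele-frequency
    signals including whole-chromosome aneuploidy, and validation statistics
    (genotype concordance against sequencing truth, variant-level sensitivity,
    patient-level diagnostic yield, inter-run reproducibility, and a
    screen-then-sequence cost model). A synthetic array-data generator with a
    complete planted-event ledger makes every stage testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    mclust
Config/testthat/edition: 3
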