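Package: clonotrace
Title: Clonal Hematopoiesis Inference from Duplex and Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking somatic clonal hematopoiesis in bone-marrow-failure
    cohorts from count-level sequencing data. Implements duplex-consensus collapsing
    and bulk somatic variant filtering down to 0.1 percent variant allele fraction,
    per-cell genotyping with allelic-dropout quantification from single-cell DNA
    panels, clone and subclone reconstruction with dropout- and doublet-aware
    merging, copy-number and copy-neutral loss-of-heterozygosity analysis from
    exome-style target counts and phased heterozygous SNP allele fractions,
    cancer-cell-fraction posteriors, and the cohort-level statistics used to relate
    clonal genotypes to clinical status. A synthetic-data generator with known
    ground truth emulates the statistical structure of all inputs so the whole
    pipeline is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
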