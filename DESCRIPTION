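Package: chipdyn
Title: Longitudinal Clonal Hematopoiesis Dynamics from Targeted Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clonal hematopoiesis of indeterminate potential
    (CHIP) from longitudinal targeted deep-sequencing data: simulation of
    multi-timepoint cohorts with UMI-tagged read counts and defined cell-line
    mixtures, UMI deduplication, a binomial somatic-variant caller with
    coverage/support/recurrent-artifact filters, whitelist-based CHIP driver
    annotation, a weighted log-linear clone-growth model with
    growing/shrinking/static classification and doubling periods,
    dominant-clone and clone-competition summaries, assay-validation
    statistics (expected mixture allele fractions, pooled error rate,
    intraclass correlation, concordance), and covariate association models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
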