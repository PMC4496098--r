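Package: autozyg
Title: Runs of Homozygosity, Inbreeding and Autozygosity Mapping for
    SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying autozygosity in livestock SNP-array data:
    PLINK-style PED/MAP input with the usual marker and sample quality
    filters, Wright's pedigree inbreeding coefficient via the tabular
    kinship method, detection of runs of homozygosity (ROH) and the derived
    genomic inbreeding coefficient FROH, principal-component stratification
    covariates computed from ROH states, single-locus linear-model
    association of ROH with inbreeding, birth year or trait transmitting
    abilities with permutation-based genome-wide thresholds, sliding-window
    haplotype homozygosity with additive and recessive models for the most
    frequent haplotype, and a pedigree/gene-dropping simulator with tracked
    identity by descent for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
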