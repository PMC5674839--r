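Package: herdscan
Title: Population Structure, Runs of Homozygosity and Selection-Signature
    Scans for SNP-Genotyped Livestock Populations
Version: 0.1.0
Authors@R:
    person("herdscan", "developers", email = "herdscan@example.org",
           role = c("aut", "cre"))
Description: A toolkit for multi-population SNP panels in livestock:
    PLINK-dialect PED/MAP input with call-rate, minor-allele-frequency and
    exact Hardy-Weinberg quality control; population-structure statistics
    (observed heterozygosity, identity-by-state distances, method-of-moments
    identity-by-descent sharing, classical multidimensional scaling,
    Weir-Cockerham F_ST with bootstrap confidence intervals, neighbor-joining
    trees); exact runs-of-homozygosity detection with genomic (F_ROH, F_HOM)
    and pedigree (F_PED, pedigree completeness) inbreeding coefficients; a
    windowed d_i selection-signature scan with empirical-percentile
    significance calling; and a seeded synthetic-data generator (Balding-
    Nichols divergence, pedigree gene-dropping with recombination) that
    provides known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
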