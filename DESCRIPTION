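Package: hetscan
Title: Heterozygosity-Rich Regions, Autozygosity and Balancing-Selection
    Scans for SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects heterozygosity-rich regions (HRRs) and runs of
    homozygosity (ROH) in diploid SNP-array genotypes using a
    consecutive-runs scanner and a multi-class homozygous-by-descent
    hidden Markov model, calls breed-level HRR/ROH islands from per-SNP
    run-sharing frequencies, scans for balancing-selection signals with
    windowed Tajima's D, and summarises cross-breed island hot spots,
    island-by-signal overlaps, one-way ANOVA of breed factors and
    pairwise Weir-Cockerham FST. Includes PLINK PED/MAP and BED/BIM/FAM
    readers, two-tier quality control with kinship-based subsampling,
    and a seeded multi-breed genotype simulator with planted
    heterozygous tracts, autozygous tracts and balancing-selection
    windows for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
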