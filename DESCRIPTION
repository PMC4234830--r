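Package: trioecy
Title: Simulation and Inference for Experimental Transitions from Outcrossing
    to Selfing in Trioecious Caenorhabditis Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward simulation of trioecious
    (male/female/hermaphrodite) nematode populations segregating a selfing
    allele at the fog-2 locus, together with the statistical machinery used
    to analyse experimental mating-system evolution: grid-based
    maximum-likelihood estimation of the outcross-fitness parameter alpha
    from allele-count time series, transition-fitness and competitive-fitness
    estimators (including a GFP heterozygote-correction algorithm for
    phenotype-scored competition assays), male-fitness estimation with
    quality-control filters, SNP diversity statistics (observed homozygosity
    and composite linkage disequilibrium from unphased genotypes), and
    synthetic-data generators with known ground truth that emulate the
    structure of the assay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
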