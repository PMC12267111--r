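Package: ursaroh
Title: Runs of Homozygosity, Genetic Load, and Demographic History from
    Whole-Genome Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conservation-genomics toolkit for diagnosing inbreeding and
    genetic load from multi-sample whole-genome genotype data, built around
    the workflow used for North American and European bears. Implements
    PLINK-style sliding-window detection of runs of homozygosity (ROH) with
    the Lencz/Purfield minimum-SNP calibration, the genomic inbreeding
    coefficient F_ROH with length-class summaries, SNP and genome-wide
    observed heterozygosity, outgroup-based allele polarization with
    partitioning of deleterious variation into potential, realized, and
    fixed load, intersection of deleterious variants with ROH tracts, and
    distillation of MSMC2/PSMC' coalescence-rate trajectories into a single
    historic effective population size. A pedigree-based genome simulator
    with crossover recombination provides cohorts with known autozygous
    tracts, load labels, and demography so that every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
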