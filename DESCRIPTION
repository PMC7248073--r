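Package: paleoburden
Title: Temporal Dynamics of GWAS Risk-Allele Burden in Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Paleoburden", "Developers", email = "paleoburden@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolutionary history of a polygenic
    trait from GWAS summary statistics and dated ancient genomes. Computes
    a per-individual mean risk-allele burden from pseudo-haploid or diploid
    genotype panels, tests its temporal trend against risk-allele
    randomization nulls, measures enrichment of ancestral alleles among
    strongly associated SNPs with a MAF-matched resampling null, estimates
    the per-generation selection trend of risk-allele frequencies under a
    Brownian model on a dated sample tree by Approximate Bayesian
    Computation with neural-network summary statistics, tests for recent
    polygenic adaptation with trait-aligned singleton density scores, and
    quantifies the trait loading of Neanderthal-introgressed tag SNPs.
    Includes a synthetic-data generator emulating every input so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    ape,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
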