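Package: metareid
Title: Re-Identification, Ancestry and Sex Inference from Host Reads in Gut
    Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much personal genetic information can be
    reconstructed from the sparse human reads that contaminate gut shotgun
    metagenome data. Implements a genotype-likelihood score under a per-base
    error model, Hardy-Weinberg null moments for score standardization,
    normal and empirical P values for matching a metagenome sample against a
    database of candidate genotypes, expected-score ancestry prediction from
    population allele frequencies, and genetic-sex prediction from the
    Y-to-X normalized read-depth ratio over non-pseudo-autosomal regions.
    Includes LD-based site pruning, samtools-pileup decoding with base
    quality filtering, a mitochondrial non-major-allele contamination
    metric, and a synthetic-data generator (Balding-Nichols population
    structure, Hardy-Weinberg genotypes, Mendelian families,
    ultra-low-coverage reads, contamination mixing) that reproduces the
    power and calibration experiments at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, SNP, Genetics, StatisticalMethod
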