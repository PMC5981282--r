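Package: ovisweep
Title: Selective-Sweep Scans and Litter-Size Marker Genetics in Sheep
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-group selective-sweep detection from pooled SNP allele
    frequencies (windowed FST with Z-standardization, pooled heterozygosity,
    allele-frequency differencing, region calling and gene annotation),
    marker population genetics (allele frequencies, polymorphic information
    content, expected heterozygosity, effective allele number, Hardy-Weinberg
    chi-square tests, EM haplotype-frequency linkage disequilibrium),
    litter-size association under a parity-by-genotype fixed-effects model
    with least-squares means and LSD significance letters, and relative
    expression by the 2^-ddCt method. Includes seeded generators that
    simulate every input the pipeline consumes, so each stage can be tested
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), GenomicRanges
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
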