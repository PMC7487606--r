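Package: cocoa
Title: Coordinate Covariation Analysis of Epigenetic Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates inter-sample epigenetic variation with a database of
    genomic region sets. Per-locus feature contribution scores (covariance,
    Pearson or Spearman association with a supervised phenotype or an
    unsupervised latent factor such as a principal component) are aggregated
    over each region set, at single-nucleotide resolution by nested averaging
    or at region resolution by overlap-proportion weighting. Significance is
    assessed by a sample-label permutation test with region-set-specific null
    distributions, a gamma method-of-moments tail approximation with an
    empirical fallback, and Benjamini-Hochberg FDR correction. Meta-region
    profiles visualise how specific the captured covariation is to a region
    set relative to its flanking genome. A synthetic-data generator produces
    planted-signal fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    jsonlite
Config/testthat/edition: 3
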