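Package: fwadapt
Title: Detecting Parallel Freshwater Adaptation from Standing Genetic Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-scan pipeline for detecting parallel adaptation across
    replicate derived populations founded from a single ancestral population.
    Implements SNP site filtering and 10-kb thinning of multi-sample VCF
    genotypes, classical population-genetic summaries (individual
    heterozygosity, folded site-frequency spectra, windowed Tajima's D,
    Weir-Cockerham FST with permutation significance), dual-method outlier
    scanning per ecotype pair (Fisher's exact test with
    Benjamini-Hochberg FDR and a PCA-Mahalanobis statistic with genomic
    inflation correction), cross-population parallelism tests including an
    exact multi-set hypergeometric intersection test, and a covariant-SNP
    procedure that identifies alleles rising in frequency in every derived
    population, with an analytic concordance expectation and a
    Wright-Fisher forward-simulation neutral null for a Z-test of excess.
    A built-in Wright-Fisher simulator generates synthetic study datasets
    with known selected loci for power and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
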