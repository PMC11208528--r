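Package: mbGWAS
Title: Genome-Wide Association Analysis of Microbiome Abundance and Beta
    Diversity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for microbiome genome-wide association
    studies on 16S rRNA amplicon data. Univariate bacterial features are
    built by taxonomic agglomeration, prevalence/abundance filtering and
    Spearman-correlation clustering; per-taxon abundance is associated
    with host genotypes by covariate-adjusted negative-binomial
    regression with randomized-quantile (Dunn-Smyth) residuals regressed
    on allele dosages; community-level (beta diversity) association uses
    a covariate-partialled distance-based F-test on Gower-centered
    Bray-Curtis dissimilarities. Includes variant quality control (MAF,
    call rate, Hardy-Weinberg exact test, imputation quality),
    significance thresholds, locus grouping with nearest-gene
    annotation, genomic-inflation diagnostics, PheWAS-style lookups of
    lead variants in external summary statistics, and a synthetic-cohort
    generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    vegan,
    vcfR,
    yaml,
    withr,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, GenomeWideAssociation, StatisticalMethod,
    Metagenomics, SNP
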