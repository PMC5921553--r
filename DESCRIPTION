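Package: famres
Title: Familial Resemblance and Variance-Components Analysis of Family Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying familial resemblance in family-based omics
    studies of nuclear families. Builds pedigree kinship (additive) and
    household relationship matrices, fits per-feature maximum-likelihood
    variance-components models partitioning phenotypic variance into polygenic
    (Vg), common-environment (Vc) and unique-environment (Ve) effects, tests
    familial effects by likelihood ratio with FDR control, and estimates
    maximal, genetic and common-environment heritability. Includes a
    cross-omic phenotypic correlation screen with Fisher-Z p-values and
    Bonferroni control, bivariate variance-components genetic correlations,
    reference-based blood cell-type deconvolution by nonnegative least
    squares, detection filtering, quantile normalization and covariate
    residualization, genomic window-overlap counting, hypergeometric
    over-representation testing, and a family-structured omics simulator with
    known variance shares for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    limma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
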