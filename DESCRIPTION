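Package: triomic
Title: Classification and Analysis of Mendelian-Inconsistent Calls in Trio Sequencing
Version: 0.1.0
Authors@R:
    person("triomic", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects Mendelian-inconsistent genotype calls (MIC) in parent-child
    trio whole-genome sequencing data, classifies them into the twelve
    (child, mother, father) genotype signatures, and separates signatures
    compatible with an inherited hemizygous deletion from error-like
    inconsistencies using repeat context, alignability, allele balance and
    normalized parental read-depth ratios. Clusters deletion-compatible MIC
    into candidate deletion regions, detects population-stratifying deletion
    regions by principal component analysis of MIC counts in genomic windows,
    writes population-specific MIC tracks, and flags candidate de novo
    mutations recurrently observed as MIC. Includes a synthetic trio-cohort
    simulator with ground truth for inherited deletions, caller errors and
    de novo mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    optparse,
    cluster,
    stats,
    utils,
    methods,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
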