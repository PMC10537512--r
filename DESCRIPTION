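Package: heterotic
Title: Heterotic Grouping of Inbred Lines from Line-by-Tester Trials and
    SNP Markers
Version: 0.1.0
Authors@R:
    person("Heterotic", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying inbred lines into heterotic groups from
    multi-environment line-by-tester testcross trials and for confronting
    those groups with SNP-marker-based diversity and clustering.  Implements
    combining-ability estimation (GCA, SCA, HSGCA) with the combined
    line-by-tester analysis of variance, the SCA- and HSGCA-based heterotic
    assignment rules with testcross-mean checks, Spearman concordance between
    grouping methods, SNP quality filtering and diversity statistics (major
    allele frequency, gene diversity, PIC, heterozygosity),
    identity-by-state distances with Ward's minimum-variance clustering,
    genotype PCA, a likelihood-based admixture estimator with the 60%
    membership rule, and Evanno's delta-K model selection.  A synthetic-data
    module generates trials and structured genotype panels with known ground
    truth so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
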