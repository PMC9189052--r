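Package: hostcomp
Title: Comparative Transcriptomics of CHO and HEK293 Expression Hosts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing recombinant-protein expression hosts
    (CHO and HEK293) at the transcriptome level. Implements transcriptome
    usage decomposition over functional gene groups, a negative-binomial
    differential-expression engine with median-of-ratios normalization,
    dispersion-trend shrinkage, Wald testing, normal-prior log
    fold-change shrinkage and a closed-form variance-stabilizing
    transformation, running-sum gene-set enrichment with permutation
    normalized enrichment scores, secretory-pathway outlier
    classification and activation-disparity ranking, and a Bayesian
    interaction regression linking post-translational-modification site
    density and enzyme expression to secreted titer improvement. A
    synthetic-data module generates count matrices, ortholog maps,
    annotations, gene sets and titers with the statistical structure the
    analysis assumes, so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, GeneSetEnrichment,
    Bayesian, Software
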