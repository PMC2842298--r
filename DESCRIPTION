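Package: pgxscan
Title: Bivariate Bayesian Genome Scans for Drug-Response Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multi-study genome-wide association analysis of
    pharmacogenomic (pre/post treatment) phenotypes. Normalized baseline and
    on-treatment measurements are recast as sum (S) and difference (D) traits;
    each SNP is scored under four hypotheses (no association, S only, D only,
    S and D) via conjugate Bayes factors with additive and dominance effects,
    averaged over a grid of prior effect-size scales and combined across
    studies by fixed-effects pooling of sufficient statistics. Posterior
    probabilities of treatment-independent versus treatment-response
    association are reported alongside frequentist single-SNP tests, genomic
    control and QQ diagnostics. Includes a multi-study synthetic-data
    generator, a baseline-adjustment (ANCOVA) bias simulation, and readers and
    writers for BIMBAM mean-genotype, dosage VCF and tabular phenotype
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    GenomeInfoDb,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    pracma,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
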