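Package: fieldomics
Title: Single-Plant Field Transcriptomics: Spatial Statistics, Normalization
    and Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-plant field omics trials, where
    individual plants of one genotype are grown on a regular grid, expression
    profiled once, and phenotyped through the season. Provides a synthetic
    field-trial generator with recorded ground truth; a regularized-log (rlog)
    normalization of per-plant RNA-seq counts with sequencing-batch fixed
    effects and empirical-Bayes shrunken plant effects; global Moran's I
    spatial autocorrelation with permutation and parametric nulls on queen
    contiguity or inverse-distance weights; coefficient-of-variation analysis
    against a fitted mean-CV^2 trend with MAD outlier flagging; beta-sigmoid
    growth-curve fitting on growing-degree-day time; single-feature
    gene-phenotype association through linear mixed models with a Gaussian
    spatial covariance (nugget + range, REML) and conditional log-link ratio
    models; and a repeated cross-validation protocol predicting phenotypes
    from expression with HSIC lasso, Spearman and median-expression feature
    selection, elastic net and random forest learners, and a permutation
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    nlme,
    minpack.lm,
    DESeq2,
    withr
Config/testthat/edition: 3
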