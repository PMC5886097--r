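Package: twinage
Title: Age Effects on the Mean, Variance and Twin Discordance of Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for age-dependent changes in gene expression
    in twin cohorts. Implements a twin-aware linear mixed model engine with
    family/zygosity covariance fitted by profiled ML/REML, likelihood-ratio
    tests for age effects on mean expression with twin-pair-preserving
    permutation adjustment stratified by exons per gene, a LOESS-based
    dispersion statistic for age-dependent expression variance, tests for
    age-related discordance between monozygotic co-twins, ACE(+age) variance
    decomposition (heritability and proportion of variance explained by
    age), cis genotype-by-age and methylation-by-age interaction scans with
    residual-permutation nulls, and Storey pi0/pi1 estimation of
    cross-tissue sharing of age effects. A synthetic twin-cohort generator
    with known ground truth makes every stage testable without access to
    controlled individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
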