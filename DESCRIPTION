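Package: chronomood
Title: Single-Gene and Epistatic Circadian Genotype Associations with
    Seasonality and Mood Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for screening circadian clock gene variants
    for single-gene and two-gene (epistatic) associations with seasonality
    and seasonal-affective-disorder phenotypes in cohort data. Builds one-way
    and pairwise genotype-combination feature spaces with reference-level
    one-hot encoding, k-nearest-neighbour imputation and SMOTE class
    balancing; runs five feature-selection methods (chi-squared, ReliefF,
    CFS, mRMR, JMI) under repeated stratified cross-validation to obtain
    consensus top-20 and stable feature sets; benchmarks four classifiers
    with grid search; fits univariate logistic and stepwise-AIC multivariate
    regressions, type-III two-way ANOVA with Tukey post hoc, and bootstrap
    causal mediation through chronotype; mines apriori association rules;
    and infers ARACNE mutual-information networks with data-processing-
    inequality pruning and bootstrap edge support to separate direct from
    chronotype-mediated genetic effects. A synthetic-cohort generator with
    Hardy-Weinberg genotypes and planted main, epistatic, sex-specific and
    mediated effects makes every stage testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car,
    igraph,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
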