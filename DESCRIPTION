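Package: irtImpute
Title: Item Response Theory Imputation of Categorical Missing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits unidimensional item response theory models (two-parameter
    logistic, graded response, nominal response) to mixed-type tabular data
    with missing cells by Bock-Aitkin marginal maximum likelihood, scores
    each case's latent trait by expected a posteriori estimation, and
    imputes missing categorical values from the model-implied category
    probabilities at the case's trait score.  Includes the evaluation
    machinery needed to benchmark categorical imputation: MCAR and MAR
    amputation of complete data, Little's MCAR test, quartile
    discretization of continuous features, per-cell F1 scoring of imputed
    values, and a synthetic-data generator built on known item banks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'response-matrix.R'
    'evaluation.R'
    'quadrature.R'
    'fit-em.R'
    'scoring.R'
    'imputation.R'
    'irt-models.R'
    'missingness.R'
    'little-test.R'
    'simulate.R'
    'presets.R'
    'utils.R'
    'variable-spec.R'
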