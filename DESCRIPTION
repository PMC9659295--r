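Package: hlsq12
Title: Scoring and Psychometric Validation of the HLS19-Q12 Health Literacy Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the 12-item short form of the European health literacy
    survey instrument (HLS19-Q12): type D and type P scoring with the
    four-level categorisation rules, classical psychometrics (Cronbach's and
    ordinal alpha, polychoric correlations, single-factor CFA for ordinal
    indicators), Rasch-family item response modelling (Partial Credit Model
    by marginal maximum likelihood, dichotomous Rasch model by conditional
    maximum likelihood, Nominal Categories Model), the associated fit and
    differential-item-functioning diagnostics (infit, Q3/aQ3/MADaQ3, SRMSR,
    PCA/t-test unidimensionality check, Andersen likelihood-ratio tests,
    item Wald tests, facets DIF models, well-conditioned-data check, a
    margin-preserving global local-independence test), weighted validity
    regressions, and a synthetic respondent generator with injectable
    violations (DIF, local dependence, response styles, missingness) so the
    whole pipeline can be exercised without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    mvtnorm,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
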