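Package: ortmap
Title: Model-Based Geostatistical Mapping of Oral Rehydration Therapy Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating subnational coverage of oral rehydration
    solution (ORS), recommended home fluids (RHF), and oral rehydration
    therapy (ORT) among children under 5 with diarrhoea, from small-denominator
    cluster survey data. Implements a Bayesian space-time binomial
    geostatistical model (Matern 3/2 spatial by AR1 temporal Gaussian field,
    Laplace approximation with hyperparameter uncertainty, joint posterior
    surface draws), definition crosswalking for non-standard RHF indicators,
    variance-inflation-factor covariate filtering, stacked-generalisation
    ensemble covariates, population-weighted aggregation to administrative
    units with uncertainty intervals and annualised rates of change,
    within-country inequality metrics (population-weighted Gini, absolute and
    relative deviation from the country mean), counterfactual
    attributable-deaths and deaths-averted analysis, and admin2-blocked
    cross-validation. A seeded synthetic-world generator provides survey,
    covariate, population and mortality inputs with the statistical structure
    the model assumes, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    glmnet,
    mgcv,
    xgboost,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
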