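Package: mbester
Title: Response-Surface, Surrogate and Film-Theory Kinetics Analysis of
    Microbubble-Mediated Esterification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational analysis of semi-pilot-scale
    microbubble esterification of high free-fatty-acid microalgae oil:
    Box-Behnken experimental design with natural/coded factor conversion,
    ordinary-least-squares quadratic response-surface fitting with ANOVA,
    lack-of-fit testing and exact box-constrained optimization, a
    from-scratch gated-recurrent-unit surrogate regressor trained by
    full-batch Adam, surrogate comparison metrics (R-squared, RMSE, MAE,
    MAPE) with parity-plot data, gas-liquid film-theory kinetics (solubility
    correlations, liquid-film mass-transfer coefficient, Hatta number,
    enhancement factors, regime classification, rate laws), Arrhenius
    activation-energy estimation, titration-based free-fatty-acid conversion
    accounting with pseudo-first-order time-course modeling, and seeded
    synthetic-data generators emulating unpublished design tables,
    rate-constant series and titration records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
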