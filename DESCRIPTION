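Package: grnnga
Title: Kernel-Regression and Genetic-Algorithm Optimization of Fertilizer Doses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Response-surface modelling and dose optimization for factorial
    fertilizer trials. Fits generalized regression neural networks (Gaussian
    kernel regression) and single-hidden-layer perceptrons trained by
    Levenberg-Marquardt to trait responses measured on a full factorial
    nitrogen x potassium x magnesium design, compares them under shared
    k-fold cross-validation with R-squared, RMSE and mean bias error, and
    couples the better surrogate to a real-coded genetic algorithm
    (roulette-wheel selection, 2-point crossover, uniform mutation, box
    constraints) to locate dose combinations that maximize each trait.
    Ships a greenhouse banana trial (36 treatments, 3 replications) as a
    packaged dataset, a synthetic factorial experiment generator with a
    known ground-truth optimum for end-to-end validation, and descriptive
    tools (trait correlations, UPGMA clustering of z-scored treatment
    profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
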