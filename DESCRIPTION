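Package: fdgradient
Title: Functional Diversity, Species Diversity and Endemicity Along
    Mountain Elevation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying plant functional diversity (Rao's
    quadratic entropy over a mixed-type Gower dissimilarity), alpha
    species diversity (Shannon-Wiener), and endemicity in vegetation
    plots sampled along Mediterranean mountain elevation gradients.
    Includes first-order jackknife sampling-adequacy estimation,
    stratification of plots into vegetation belts and topographic
    position index groups with one-way ANOVA and post hoc comparisons,
    a repeated k-fold cross-validation harness comparing eleven
    regression families, fixed-df generalized additive models with
    two-block ANOVA tables and partial-effect curves, and a synthetic
    community generator with recorded ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    mgcv,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster
Config/testthat/edition: 3
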