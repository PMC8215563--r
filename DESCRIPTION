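Package: mealcurve
Title: Simulation and Multi-Level Modelling of Within-Meal Food Intake Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying eating behaviour from plate-scale (universal
    eating monitor) recordings of food weight over the course of a meal.
    Simulates cohorts of hierarchical food-removal curves with participant- and
    meal-level random intercepts and slopes, device "cutlery spike" artifacts
    and Hardy-Weinberg genotype exposures; smooths raw curves by a
    running-minimum rule; fits three-level linear mixed models by REML (random
    slopes or random intercepts only) and extracts per-meal BLUP eating speeds;
    computes time-referenced intra-class correlations, design effects for
    repeated meals per person, and two-sample power and sample-size
    calculations; and codes BMI, FTO rs9939609 genotype and dietary-fat
    exposures with descriptive cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
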