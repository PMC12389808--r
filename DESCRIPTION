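Package: capflow
Title: Capillary Flow Profiling and Classification for Paper Microfluidics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for capillary wetting-front dynamics on
    paper-based microfluidic strips, aimed at classifying astringency
    (tannic acid) intensity from flow profiles. Provides a seeded synthetic
    experiment generator that renders grayscale flow videos, wetting-front
    extraction from frame stacks with monotone enforcement, assembly of
    raw/replicate-averaged/min-max-normalized profile datasets, reduction
    of each profile to a single Lucas-Washburn square-root-of-time fit
    coefficient, grid-searched stratified 3-fold cross-validated comparison
    of eight classifier families, and one-way ANOVA with Tukey HSD compact
    letter displays of the fit coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    MASS,
    nnet,
    png,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
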