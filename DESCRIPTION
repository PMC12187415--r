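Package: fishsde
Title: Data-Driven Stochastic Modelling of Collective Exploration in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies visual cues (visual-field opacity and optic flow) and
    intermittent exploration episodes from tracked two-dimensional fish
    trajectories, identifies a one-dimensional stochastic differential
    equation for interindividual distance by Kramers-Moyal estimation with
    LASSO-initialised stepwise sparse regression, analyses the implied
    bistable potential landscape, and runs Euler-Maruyama in-silico
    experiments with the statistical summaries (two-way ANOVA with effect
    sizes, interquartile-range outlier rule, linear regression) needed to
    compare illumination and group-size conditions. A synthetic-data
    generator emulates the recording setup (30 Hz, 18000 frames, 60 cm
    circular arena, groups of 1-3 fish) so the whole pipeline runs without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
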