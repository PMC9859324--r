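Package: oxylife
Title: Bayesian Spatial Analysis of Ambient Oxygen and Regional Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An ecological-regression toolkit for quantifying the association
    between ambient oxygen partial pressure and regional life expectancy.
    Builds inverse-distance spatial weights between region centroids, gates
    model choice on a permutation test of Global Moran's I, and fits Bayesian
    regressions with either conditionally autoregressive (CAR) or exchangeable
    (IID) region-level random effects by a from-scratch Gibbs sampler, with
    DIC-based covariate screening. Includes the descriptive machinery for a
    140 mmHg hypoxia dichotomization (normality-routed summaries and
    Mann-Whitney comparisons), Ward-linkage hierarchical clustering of
    cause-of-death years-of-life-lost profiles with ANOVA/Kruskal-Wallis
    between-cluster testing, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    ape,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
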