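Package: flatmate
Title: Mating Behaviour, Mate Choice and Stylet Morphometrics in
    Macrostomum Flatworms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mating behaviour, hybridization and mate
    choice in the free-living flatworms Macrostomum lignano and
    M. janickei. Extracts behavioural traits (copulation latency,
    duration, interval, suck metrics, fecundity) from frame-scored event
    logs; computes coefficients of variation on log-normal and raw
    scales; runs the group comparisons (one-way ANOVA with Tukey HSD,
    Kruskal-Wallis with Bonferroni-corrected pairwise Wilcoxon tests);
    implements the mate-choice statistics, including repeated G-tests of
    goodness-of-fit with heterogeneity decomposition and a mating-rate
    adjusted Hardy-Weinberg-style null for copulation-type frequencies;
    and provides landmark-based geometric morphometrics of the stylet
    (generalized Procrustes alignment, sliding semilandmarks, relative
    warps, thin-plate-spline deformation grids). A stochastic simulator
    generates synthetic pair logs, mating-arena drops and stylet landmark
    configurations with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
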