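Package: forestsdm
Title: Forest-Structure Drivers of Species Distributions via Presence-Background Maxent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how forest structure and composition drive
    regional-scale species distributions, built around forest-inventory plot
    data and presence-only occurrence records. Derives plot-level structural
    and compositional variables (basal area, stem densities, large-tree and
    dead-tree densities, diameter heterogeneity), interpolates them to
    occurrence and background points at home-range-dependent scales, fits
    L1-regularized maximum-entropy (Maxent) presence-background models with
    linear, quadratic and hinge features, tunes them by AICc, calibrates
    discrimination against null models, and relates per-variable training
    gain to species functional traits (roosting ecology, wing loading,
    aspect ratio) through linear models and ANOVA with Holm correction.
    Includes a synthetic-data module that generates forest landscapes,
    inventory plots, climate surfaces and virtual species for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
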