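Package: npqdyn
Title: Kinetics of Non-Photochemical Quenching Relaxation and Its Canopy-Scale Cost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping the relaxation of non-photochemical
    quenching (NPQ) from chlorophyll-fluorescence pulse series. Computes NPQ
    and Fv/Fm from dark-adapted and light-adapted fluorescence, fits the
    double-exponential relaxation model to extract the qE, qM and qI
    amplitudes and time constants, applies quality filters and technical
    replicate averaging, derives daily weather covariates (vapor pressure
    deficit, morning and 3-day aggregates), and provides the inference layer
    used for genotype screening: genotype-by-day ANOVA, stepwise-AIC
    environmental models, canonical correlation analysis with Wilks' Lambda,
    per-day PCA, and a nested-AIC linear mixed-effects screen against a
    reference genotype. A dynamic canopy photosynthesis simulator prices slow
    NPQ relaxation and Rubisco activation as percent daily carbon
    assimilation under fluctuating light. A synthetic-data module generates
    fluorescence traces, weather series, multi-genotype experiments and
    canopy light drivers with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
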