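Package: wingFA
Title: Fluctuating-Asymmetry Analysis and Modifier-Screen Pipeline for
    Bilateral Size Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fluctuating asymmetry (FA) of a bilateral size trait
    from repeated left/right measurements using the measurement-error-corrected
    FA10a index, computed from the two-way mixed-model ANOVA (individual random,
    side fixed, replicates in the residual). Provides the quality-control
    battery used in FA studies (Shapiro-Wilk and Lilliefors normality of signed
    asymmetry, bias-adjusted skewness/kurtosis thresholds, iterative outlier
    elimination, size-dependence check), series-controlled F-test comparisons
    with Holm correction and fold-change classification for two-stage
    enhancer/suppressor modifier screens, downstream correlation analyses, and
    a synthetic-data generator with the exact variance-component structure the
    ANOVA assumes, so every stage is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
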