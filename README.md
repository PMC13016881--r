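# wingFA

Fluctuating-asymmetry (FA) analysis for bilateral size traits, and the
screening machinery built on top of it.

## What problem this solves, and for whom

Fluctuating asymmetry — small, random, non-directional left–right
deviations of a bilaterally symmetric trait — is the standard readout of
*developmental noise*: how precisely a genotype develops under fixed
conditions. Quantifying it correctly is notoriously fiddly because
measurement error behaves statistically exactly like FA, and because
directional asymmetry and antisymmetry must be separated from it.

`wingFA` is for biologists running FA studies on repeated left/right
measurements (the motivating case is *Drosophila* wing length, the
distance between two wing landmarks, each wing digitized twice), and in
particular for **modifier screens**: comparing the FA of many genotypes
against per-series internal controls to find enhancers and suppressors of
a destabilized background.

## The estimator at its core

Each genotype sample (n individuals × 2 sides × r replicate measurements)
is decomposed by the balanced two-way mixed-model ANOVA — individual
random, side fixed, replicates in the residual:

    m_isr = mu + I_i + D_s + A_is + e_isr

The individual×side interaction A is the true FA; the residual e is
measurement error. The FA10a index removes the error component:

    FA10a = (MS_interaction − MS_residual) / r

an unbiased estimate of the FA variance sigma²_FA, in squared trait
units. Around the estimator the package provides:

* `fa_fit()` — the central fitting function (S3 object with `print`,
  `summary`, `coef`, `residuals`, `fitted`, `simulate`, `plot` methods),
  including directional asymmetry and its F test;
* `qc_sample()` — the QC battery on signed asymmetries: Shapiro–Wilk +
  Lilliefors normality, bias-adjusted skewness/kurtosis bounds
  (|G1| ≤ 0.5, |G2| ≤ 3), capped iterative outlier elimination,
  `size_dependence()` allometry check;
* `compare_fa()` — exact two-sided F test on interaction mean squares,
  with FA10a fold changes;
* `run_series()` / `aggregate_two_stage()` / `run_pipeline()` — the
  series-controlled screen: Holm correction within series, fold-change
  classification (decreasing / enhancing / neutral / lethal /
  unmeasurable), two-stage confirmation, TSV + JSON artifacts;
* `simulate_sample()` / `simulate_screen()` / `screen_scorecard()` — a
  generator with the exact variance-component structure the ANOVA
  assumes, for calibration and power exploration against known truth.

See the vignette (`vignettes/wing-asymmetry-screen.Rmd`) for the model,
the design decisions, and the known limitations.

## Worked example

```r
library(wingFA)

# a destabilized control genotype and a deficiency that enhances its FA
ctrl <- simulate_sample(sigma_fa = 21.2,           seed = 101, genotype = "CTRL+TG")
mut  <- simulate_sample(sigma_fa = 21.2 * sqrt(5), seed = 102, genotype = "Df+TG")

fa_fit(ctrl)
#> FA fit: CTRL+TG (series S1), n = 30, r = 2
#>   FA10a        = 474.9
#>   ME variance  = 4.094
#>   DA (R - L)   = 6.861  (F = 1.481, p = 0.2335)

compare_fa(fa_fit(mut), fa_fit(ctrl))
#> FA comparison (interaction mode): Df+TG vs CTRL+TG
#>   F = 5.451 on (29, 29) df,  two-sided p = 1.75e-05
#>   FA10a fold change = 5.47 (increase)

qc_sample(ctrl)
#> QC report: CTRL+TG (series S1)
#>   n 30 -> 30
#>   Shapiro-Wilk p = 0.8851, Lilliefors p = 0.7354
#>   G1 = 0.3222, G2 = -0.4138
#>   PASS
```

Reading the numbers: the control's FA10a of ≈475 µm² is its
developmental-noise variance after removing the ≈4 µm² per-measurement
error variance (the generating values were sigma_fa = 21.2, so
sigma²_FA ≈ 450, and sigma_me = 2). The deficiency genotype, generated
with 5× that FA variance, is recovered with a fold change of 5.47 and is
decisively significant on the exact (29, 29)-df F test. The QC report
shows a clean sample: both normality tests comfortably non-significant
and both moment statistics inside their acceptance windows, so no
individual is removed.

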