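---
title: "Measuring developmental noise: FA10a estimation and modifier screening with wingFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring developmental noise: FA10a estimation and modifier screening with wingFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingFA)
```

## The problem

Bilaterally symmetric traits develop twice from the same genome in the same
organism. Small, random, non-directional left–right deviations — fluctuating
asymmetry (FA) — therefore measure *developmental noise*: the residual
imprecision of development after genotype and environment are held fixed.
In insect-wing studies the trait is typically a linear wing length, the
distance between two homologous landmarks, and the experimental unit is a
genotype sample of ~30 individuals with both wings measured.

Two confounds make naive FA estimates useless:

* **Measurement error (ME)** behaves statistically exactly like FA
  (non-directional random variation between repeated measurements), so each
  wing must be measured at least twice and ME partitioned out.
* **Directional asymmetry (DA)** — a consistent mean R−L offset — and
  **antisymmetry** — bimodal R−L differences — are different phenomena that
  must be detected and separated, not absorbed into the FA estimate.

`wingFA` implements the standard solution: a balanced two-way mixed-model
ANOVA per genotype sample, the measurement-error-corrected **FA10a** index
derived from it, a quality-control battery on the signed asymmetries, and,
on top of the estimator, the series-controlled F-test/Holm/fold-change
machinery of large enhancer–suppressor modifier screens.

## The model

For measurement $m_{isr}$ of individual $i$ (random), side
$s \in \{L, R\}$ (fixed), replicate $r$:

$$m_{isr} = \mu + I_i + D_s + A_{is} + \varepsilon_{isr}$$

with $I_i \sim N(0, \sigma^2_{ind})$ the individual size effect,
$D_R - D_L = \delta_{DA}$ the fixed side (directional-asymmetry) offset,
$A_{is} \sim N(0, \sigma^2_{FA})$ the individual-by-side interaction — the
*true fluctuating asymmetry* — and
$\varepsilon_{isr} \sim N(0, \sigma^2_{ME})$ the replicate measurement
error.

For a balanced block ($n$ individuals × 2 sides × $r$ replicates) the
expected mean squares are

| stratum | df | E[MS] |
|---|---|---|
| side | 1 | $\sigma^2_{ME} + r\,\sigma^2_{FA} + n r\,\delta_{DA}^2/2$ |
| individual | $n-1$ | $\sigma^2_{ME} + r\,\sigma^2_{FA} + 2r\,\sigma^2_{ind}$ |
| individual × side | $n-1$ | $\sigma^2_{ME} + r\,\sigma^2_{FA}$ |
| residual | $2n(r-1)$ | $\sigma^2_{ME}$ |

so the interaction stratum alone overestimates FA by one unit of
measurement-error variance, and

$$\mathrm{FA10a} = \frac{MS_{int} - MS_{res}}{r}$$

is an unbiased estimate of $\sigma^2_{FA}$, in squared trait units. The
test suite verifies this decomposition against a brute-force loop oracle
and against `anova(lm(...))`, and verifies unbiasedness by simulation
(2000 samples at $\sigma_{FA} = 2$, $\sigma_{ME} = 1$, $n = 30$, $r = 2$).

Two numerical points:

* Mean squares are computed by the closed-form balanced decomposition
  (grand/marginal/cell means), not by a general linear-model solver: it is
  exact, fast, and the balanced block is guaranteed upstream by
  `assemble_samples()`, which drops (never imputes) individuals with
  incomplete records.
* A raw FA10a can be negative (interaction MS below residual MS, expected
  under pure measurement error). It is reported as-is with a
  `negative_flag`, never clamped: clamping would bias every
  simulation-based calibration and every downstream mean.

Directional asymmetry is reported as the signed mean R−L difference with
the mixed-model F test of the side effect over the interaction stratum
(df $1, n-1$).

## Comparing FA between genotypes

The screen needs a test for "genotype A is more/less asymmetric than
genotype B". A difference of FA10a values is not F-distributed, so the
default statistic is the **ratio of interaction mean squares**,
$F = MS_{int}^{(A)} / MS_{int}^{(B)}$ with $(n_A - 1, n_B - 1)$ df. Under
equal $\sigma^2_{FA}$ *and* equal $\sigma^2_{ME}$ this is exactly
F-distributed; equal ME is reasonable when both samples come from the same
measurer and protocol, as within an experimental series. The p-value is
two-sided (twice the smaller tail, capped at 1) because a modifier screen
seeks both enhancers and suppressors. The test suite confirms exactness:
over 10,000 null pairs the rejection rate at $\alpha = 0.05$ falls in
[0.04, 0.06] and the p-values are KS-uniform.

A documented alternative (`mode = "fa10a"`) tests the FA10a ratio itself
with the same nominal df; it is approximate (a ratio of MS *differences*)
and unavailable when either estimate is non-positive. It exists for
sensitivity analysis, e.g. when ME is suspected to differ between groups.

The *fold change* reported alongside the test is always the FA10a ratio —
the biologically meaningful quantity, since FA10a is the developmental
noise variance. When the reference FA10a is non-positive the fold change
is undefined and flagged; the comparison is still reported on the MS
ratio.

## The QC battery

FA inference assumes the per-individual signed asymmetry
$d_i = \bar{R}_i - \bar{L}_i$ is approximately normal. Departures flag
either gross measurement errors (single wild values) or genuine
interference such as antisymmetry (bimodality). `qc_sample()` applies, to
each genotype sample:

* Shapiro–Wilk and Lilliefors tests at $\alpha_{norm} = 0.05$ each
  (Lilliefors via the `nortest` package, Dallal–Wilkinson p-values);
* bias-adjusted skewness $G_1$, accepted in $[-0.5, 0.5]$;
* bias-adjusted *excess* kurtosis $G_2$, accepted in $[-3, 3]$. The bounds
  are read on the excess scale (normal = 0) because raw kurtosis below
  $-3$ is impossible — the only reading under which both bounds are
  attainable. The lower bound doubles as an implicit antisymmetry screen
  (bimodal $d$ is strongly platykurtic), so no separate dip test is used.

While a sample fails any criterion and fewer than `max_removals = 3`
individuals have been removed, the individual with the largest robust z
score $|d_i - \mathrm{median}(d)| / \mathrm{MAD}$ is eliminated and the
battery re-run. The rule is deterministic and auditable (ties resolve to
the first index, and the fallback scale when MAD is zero is the absolute
deviation itself). A sample still failing at the cap is flagged
`cap_reached`, never silently passed; one that would shrink below
`min_n = 10` is flagged `unusable`. QC alters membership only — never a
measurement value.

Two properties of this battery matter for interpreting screens. First,
a planted gross error (a 10× digit-slip in one measurement of a clean,
QC-passing sample) is identified as the sole removal in ≈95–98% of cases
(measured in the test suite). Second, the thresholds are *tight* for
perfectly clean Gaussian samples at $n = 30$: $|G_1| > 0.5$ alone has
≈25% probability, so roughly a third of clean samples lose 1–3
individuals. This trimming is deliberate (it is what keeps gross errors
out) but costs a few points of downstream comparison power on error-free
data — visible in the screen scorecard below.

A separate allometry check, `size_dependence()`, correlates FA10a with
group mean size across genotypes: a *positive* correlation would warn that
apparent FA differences might be size allometry; a negative or null one
supports genuine developmental-instability differences.

## The modifier screen

Absolute FA levels drift between experimental batches, so screens are
organized in *series* (up to 25 test genotypes), each carrying its own
internal controls: a positive control (the destabilized background alone)
and, in the replication stage, a negative control (undestabilized
background). All comparisons are within-series:

1. each deficiency's destabilized sample is compared with the series
   positive control (`compare_fa`);
2. raw p-values are Holm-adjusted *within the series family*
   (`holm_adjust`, a thin wrapper over `stats::p.adjust`);
3. classification at $\alpha = 0.05$: adjusted $p < \alpha$ and fold
   change $< 1$ → `decreasing` (suppressor of destabilization), fold
   $> 1$ → `enhancing`, otherwise `neutral`. Genotypes with no sample or
   fewer than `min_n = 10` individuals are `lethal`; samples the QC
   battery cannot salvage are `unmeasurable`.
4. the secondary (replication) stage repeats 1–3 on fresh data for the
   primary hits plus a few carried neutrals, and additionally compares
   each deficiency-alone genotype with the negative control — a separate
   Holm family, since it tests a different null (does the deficiency
   perturb FA *by itself*?).
5. `aggregate_two_stage()`: a deficiency is a **confirmed modifier** only
   if significant with the same direction in both stages.

The $\alpha = 0.05$ on adjusted p-values, the lethality rule (absent
genotype or $n <$ 10), and the secondary Holm family separation are
package defaults, all configurable; each is serialized into every output
artifact's provenance header by `run_pipeline()`.

## The synthetic-data generator

`simulate_sample()` draws exactly from the model above, so every stage of
the package can be tested against known truth. Defaults describe a
realistic wing-length trait in micrometres: `mu_size = 2500`,
`sigma_ind = 50` (2% CV), `delta_da = 2`, `sigma_fa = 3` (wild-type-like
developmental noise), `sigma_me = 2` (landmark digitization error;
repeatability far above 99%), `n = 30` individuals, `r = 2` replicates.
`screen_scenario()` builds multi-series screens on a destabilized baseline
(`sigma_fa = sqrt(50) * 3`, i.e. ≈50× the wild-type FA variance, within
the 30–70-fold range typical of strongly destabilized systems); each
deficiency scales $\sigma^2_{FA}$ by its true fold change, and lethal
deficiencies emit no individuals. One global seed expands into per-sample
substreams by stable hashing of (stage, series, genotype), so adding a
genotype to a scenario never perturbs the draws of the others.

What the generator does *not* emulate: non-Gaussian measurement-error
tails, within-series batch drift, digitization artifacts correlated
between the two replicates of a wing, genetic-background heterogeneity
among individuals, and missing/damaged wings (incomplete individuals are
instead exercised directly in the I/O tests). Passing tests therefore
demonstrate correctness of the estimator and the decision machinery under
the model's own assumptions — not robustness to every pathology of real
slide-scanned data; the QC battery is the guard for those.

`screen_scorecard()` runs a complete two-stage screen on a scenario and
scores confirmations against the truth table. Under the package's study
conditions (2 series × 25 deficiencies, planted fold-5 enhancers and
fold-0.2 decreasers, $n = 30$) the acceptance suite measures a mean of
roughly 4.6–4.8 of 6 planted modifiers correctly confirmed, with false
confirmations in ≈1–2% of screens. The per-comparison F test itself is at
its theoretical power (≈0.87 per stage for a fold-5 enhancer under
Holm-25); the gap to the naive expectation is the deliberate QC trimming
described above plus the two-stage confirmation requirement.

## Problem sizes in the test suite

Unit tests use blocks of $n$ = 2–10 and small simulations (hundreds of
replicates). The deeper statistical checks use 2000 samples for estimator
recovery, 10,000 pairs for test calibration, 10,000 series for Holm FWER,
and 100 full two-stage screens for the scorecard — sizes chosen so the
whole suite completes in about a minute on one core while keeping
Monte-Carlo standard errors well below the tolerances being asserted.

## Known limitations

* Only balanced designs are supported; unbalanced data call for REML
  variance components, out of scope here (incomplete individuals are
  dropped).
* Only a linear size trait is analyzed; shape FA (geometric
  morphometrics) is a different pipeline.
* Other FA indices (FA1, FA4a, FA8a, …) are not provided: FA10a is the
  one that partitions out measurement error from repeated measurements.
* The interaction-MS F test assumes comparable measurement error between
  the two samples; when that is doubtful, use `mode = "fa10a"` as a
  sensitivity check rather than a primary test.
* p-values attached to the association correlations are descriptive
  companions (the correlations are the quantities of interest), and the
  deficiency-span correlation is unit-agnostic (bp or band count).
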