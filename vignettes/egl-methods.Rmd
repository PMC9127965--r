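---
title: "Methods: glycemic load estimation and model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycemic load estimation and model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egload)
```

## The quantities

Postprandial glucose handling is summarised by three related quantities.
The **incremental area under the curve (IAUC)** integrates a subject's
blood-glucose excursion above the fasting baseline over the two hours
after eating. The **glycemic index (GI)** normalises a food's IAUC by the
same subject's IAUC after a glucose-solution reference, in percent, which
removes between-subject differences in glucose handling. The **glycemic
load (GL)** multiplies GI by the available carbohydrate (total
carbohydrate minus dietary fiber, g) of one serving and divides by 100,
so it measures the glycemic effect of a realistic portion rather than of
a fixed carbohydrate dose.

The **estimated glycemic load (eGL)** is a prediction of GL from the
nutrient label alone:

$$\mathrm{eGL} = a + b\,(\mathrm{carb}-\mathrm{fiber}) - c\,\mathrm{fat}
  - d\,\mathrm{protein}^2 - e\,\mathrm{fiber}^2 .$$

The linear carbohydrate term carries the load ($b>0$ is enforced); fat,
protein and fiber slow gastric emptying and glucose absorption, which the
equation represents as subtractions — quadratic in protein and fiber, so
large amounts of either damp the predicted response more than
proportionally.

## IAUC geometry

`incremental_auc()` uses the *baseline-cut* trapezoidal rule: the curve is
linearly interpolated between measurements, area below the fasting
baseline (the value at time 0) is ignored, and any segment crossing the
baseline is split at the interpolated crossing so that only its positive
part contributes. This is the standard choice in GI methodology, where
late-curve dips below fasting glucose should not cancel the earlier
excursion. The implementation is closed-form per segment; the test suite
checks it against fine-grid numeric integration of the positive part of
the interpolated excess curve (relative error $10^{-6}$, with a
1 mg·min/dL absolute floor because curves with essentially no positive
excursion make a relative criterion meaningless) and verifies invariance
to adding a constant to all glucose values.

A subject's GI denominator is the mean of that subject's glucose-solution
reference tests only. Steamed-rice reference tests are accepted and
stored under their own reserved id (`RICE_REF`) but do not enter the
denominator: the GI definition names the glucose solution. Per-food GI is
the mean of the per-subject ratios (not the ratio of mean IAUCs), because
the per-food dispersion reported in the source tables is a dispersion of
per-subject values.

## Recovering the eGL constants

The constants $a\ldots e$ of the eGL equation were not published. Because
eGL is linear in the five regressors $\{1,\ \mathrm{carb}-\mathrm{fiber},\
-\mathrm{fat},\ -\mathrm{protein}^2,\ -\mathrm{fiber}^2\}$, they can be
recovered by ordinary least squares on the bundled 24-food table, whose
eGL column was computed with the original constants and rounded to
integers. `fit_egl()` does this (QR decomposition, explicit rank check —
at least five linearly independent nutrient profiles are required). The
fit reproduces every printed eGL within 0.41 GL units, i.e. well inside
the rounding radius, and on data generated exactly from known constants
the recovery is exact to numerical precision. The recovered set is stored
as a packaged config (`default_egl_coefficients()`) and can be overridden
by any user-supplied `egl_coefficients()`.

## Classification bands

Low/medium/high bands use closed bounds: GI ≤ 55 low, GI ≥ 70 high;
GL ≤ 10 low, GL ≥ 20 high. An alternative convention defines high GI as
*exceeding* 70; no food in the bundled table sits exactly at 70, so the
data cannot distinguish the two, and the bands are configurable
(`glycemic_bands()`). Displayed GI/GL/eGL values are rounded to the
nearest integer, halves away from zero (`round_glycemic()`), matching the
printed tables; all internal computation keeps full precision. One
bundled food (corn salad) has printed GI 23 and available carbohydrate
15 g, giving GL 3.45 against a printed GL of 4 — attributable to the GI
having been rounded before the printed GL was computed; the
reproduction tests therefore allow ±1 on printed GL (±0.5 for at least
22 of 24 foods) and the value is transcribed, not "corrected".

## Validation machinery

**Transportability.** Whether the model's development cohort differs from
the validation cohort is assessed per characteristic with two-sample
t-tests computed from the published summary statistics (pooled variance
by default, matching the era's default package behaviour; Welch via
`var_equal = FALSE`) and a chi-square test for the sex proportion. Only
summary statistics are needed, so the bundled cohort table suffices.

**Calibration and discrimination.** The source analysis dichotomised
events and ran logistic regression, a Hosmer–Lemeshow test and an AUROC,
but did not state the outcome definition. This package's interpretation —
flagged here deliberately — is *observed high GL*: an event counts as
positive when its measured GL is at or above the high-GL band edge (20).
The eGL score enters a univariable logistic fit (maximum likelihood via
iteratively reweighted least squares, with explicit convergence,
score-gradient and complete-separation checks); the Hosmer–Lemeshow
statistic uses 10 near-equal "deciles of risk" with χ² referred to
`groups − 2` degrees of freedom, merging any group whose expected event
or non-event count is zero; the AUROC is the Mann–Whitney concordance
(ties half-weighted) with a Hanley–McNeil 95% interval clipped to [0, 1].
Subgroups follow the source design: sex, BMI at the Asian-population
cut of 23 kg/m², and percent body fat dichotomised at 25% (men) / 32%
(women) — the body-fat thresholds were not published and are
configurable. A stratum with a single outcome class is reported as not
estimable rather than failing the run. Because the original per-subject
data are unpublished, the package does not attempt to reproduce the
original χ² and AUROC values; the machinery is instead validated by
properties: type-I error of the Hosmer–Lemeshow test in a calibrated
simulation, exact agreement of the AUROC with brute-force pairwise
concordance, and a null AUROC of one half.

**Agreement.** Pearson correlation (two-sided t p-value) and the simple
regression of measured on estimated GL. Two scales matter and should not
be conflated: across the 24 *per-food means* the correlation is high
(r ≈ 0.90) and the regression line has slope ≈ 1.64 and intercept
≈ −9.27; across the 192 *per-event* pairs the correlation is attenuated
by within-food dispersion to ≈ 0.71 (R² ≈ 0.51). The simulator's
event-level draws reproduce the attenuated value, and a closed-form
prediction (`attenuated_event_correlation()`, using exact
truncated-normal within-food moments) matches the simulation to ~0.001.

## The synthetic-data generator

`simulation_config()` defaults are the validation study's own
conditions: 20 subjects (sex-balanced), 8 events per food, measurements
at 0/15/30/45/60/90/120 min, fasting baseline Normal(92.8, 4.78) mg/dL.
Quantities the study did not report needed one-time choices:

* **Per-event GL** is drawn directly from each food's published
  mean ± SD (Normal, truncated at zero by inverse-CDF sampling, so the
  draw is deterministic given the RNG stream), rather than via simulated
  curves: the study publishes GL dispersion, not curve dispersion.
  Truncation at zero adds a small positive bias for foods whose SD is
  large relative to the mean; this is documented, not corrected, and the
  analytic attenuation check accounts for it exactly.
* **Curve shape** is a two-parameter gamma-like pulse
  $(t/t_p)^k e^{k(1-t/t_p)}$ peaking at $t_p = 35$ min — inside the
  30–45 min window where postprandial peaks occur — scaled so the
  noiseless curve's IAUC equals its target exactly (the pulse is
  non-negative and zero at baseline, making trapezoidal scaling exact).
  Measurement noise (SD 5 mg/dL, the order of a capillary glucometer's
  error) is added to post-baseline points. The shape is configuration,
  not science: only the sampling grid is reported.
* **Reference IAUC** per subject is Normal(3800, 600) mg·min/dL: 3800 is
  a typical 2-hour IAUC for 50 g glucose in healthy adults and sits near
  the centre of the values implied by the published food IAUC/GI pairs;
  the SD reflects the within-subject repeatability that motivates
  duplicate reference tests.
* **Cohort characteristics** are drawn independently from the published
  means and SDs, except that weight is recomputed as
  BMI × (height/100)², keeping the three mutually consistent.

What the generator does *not* emulate: correlations between subject
characteristics, between-subject differences in glucose handling beyond
the reference-IAUC draw, food-by-subject interactions, day effects, and
the separation of within-food GL variance into biological and
measurement components (the study reports them pooled, so the simulator
treats them as one Normal component). Passing tests therefore show that
the pipeline's statistics behave correctly under the study's *reported*
distributional structure, not that they would be unbiased under every
real-data complication.

## Numerical choices and problem sizes

Degenerate inputs are errors with informative messages (empty curves,
non-monotone times, negative available carbohydrate, rank-deficient
designs, single-class outcomes); strata degenerate only at run time are
reported as not estimable. The test suite sizes its simulations for
tight Monte-Carlo error at interactive runtimes: 500 replicates of the
192-event simulation (MC standard error of the mean correlation
≈ 0.0015), 1000 replicates at n = 500 for the Hosmer–Lemeshow type-I
error, 1000 random curves against the IAUC oracle, and 200 replicates
for the GI-recovery and cohort-mean checks. All generators are
byte-identical under a fixed seed.

## Known limitations

The eGL constants are recovered from rounded integer responses, so they
carry that rounding error (bounded by the 0.41 max residual). The
validation of calibration/discrimination is property-based, not a
reproduction of the original subject-level values, which would require
the unpublished raw data. The transportability t-tests recompute
p-values from printed (rounded) summaries and can differ from the
originals in the second decimal. And eGL itself is a label-based
prediction: it cannot see preparation, food matrix or meal-context
effects that move measured GL for identical labels.
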