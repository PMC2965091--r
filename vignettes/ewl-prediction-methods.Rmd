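---
title: "Methods: linear and neural correlation models for excess weight loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and neural correlation models for excess weight loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Laparoscopic adjustable gastric banding (LAGB) produces highly variable
weight loss, and which patients benefit is hard to anticipate.  This
package implements a prediction workflow for two-year percent excess
weight loss (EWL) in adult women, from pre-surgical age and MMPI-2
psychometric T scores: a best-subset multiple linear regression, a
dual-network correlation-maximization model that relaxes the linearity
assumption, and an evaluation layer (quartile confusion matrices, ROC
analysis, repeated 3-fold cross-validation).  Because no patient-level
data set of this kind is publicly deposited, a synthetic cohort generator
with a plantable outcome is a first-class, tested component: every
stage's statistical behaviour is verified against known ground truth.

## Outcome definition

EWL at follow-up is
$$\mathrm{EWL} = 100\,\frac{w_{pre} - w_{cur}}{w_{pre} - w_{ideal}},$$
with the ideal weight from the female Lorentz formula
$w_{ideal} = h - 100 - (h-150)/2$ (height $h$ in cm, weights in kg).
EWL is linear in the current weight, negative under weight gain and above
100 below ideal weight.  Patients are divided at the empirical quartiles
of EWL (linear-interpolation quantiles, type 7); a value equal to a
threshold belongs to the lower quartile, matching the convention that the
printed thresholds are quartile *upper* bounds.

## Synthetic cohort generator

`generate_cohort()` emulates the cohort the analysis assumes:

* **Marginals.** Age 41.7 ± 11.3 y (truncated at 18), pre-surgical BMI
  42.5 ± 5.1 kg/m² (truncated to [25, 70]), heights 162 ± 6 cm
  (truncated to [140, 190]; heights are simulated only so the
  Lorentz/EWL arithmetic round-trips — the source tables report none),
  and 28 MMPI-2 scale T scores with mean 50 and SD 10.
* **Dependence.** Scales share an exchangeable correlation of 0.3 within
  the validity / clinical / content families and are independent across
  families.  No published inter-scale covariance accompanies the study
  tables, so this is a modelling choice: it keeps collinearity present
  but mild (VIF well below 5, the regime the linear model's diagnostics
  report), which makes subset selection non-trivial without being
  degenerate.
* **Planted outcome.** `plant_outcome()` builds an index
  $t = \sum_i w_i z_i$ over standardized predictors (defaults: age, Pa,
  Asp, TpA with weights $-0.148, -0.239, -0.260, 0.182$, the signs and
  relative sizes of the study's standardized coefficients), applies a
  link — identity, or $\tanh(1.5\,t/\mathrm{sd}(t))$ for a saturating
  monotone nonlinearity — and adds Gaussian noise with variance chosen so
  that $\mathrm{cor}(\text{link}, \mathrm{EWL})^2$ equals `target_r2`
  (default 0.365, the nonlinear fit share of the study).  The result is
  mapped affinely to mean 48.19, SD 19.71 percent.  Noise is drawn from
  per-record truncated normals so every EWL lands in [0, 100] without
  clipping planted values; at the default moments the truncation is rare
  (≈2 SD out) and perturbs the planted correlation by well under the
  test tolerances.  Post-surgical weights are back-solved so that
  recomputing EWL from weights and height reproduces the planted value
  exactly.  The noise is Gaussian throughout; nothing in the source
  material constrains its shape.

What the generator does *not* emulate: item-level MMPI-2 responses,
validity-scale invalidation, real covariance between psychometrics and
age/BMI, measurement error in weights, or attrition.  Passing tests
therefore demonstrate that the *machinery* recovers known structure at
realistic moments — not that the fitted numbers of any real cohort are
reproduced.

## Best-subset linear model

All subsets of 1–4 candidates (age, BMI, 28 scales → 31,930 models) are
fit by least squares on sufficient statistics (covariance algebra), the
cap of 4 reflecting the records-per-variable rule a 172-record data set
supports.  Models with overall F-test p ≥ 0.05 are excluded; the rest are
ranked by R² descending, ties broken by smaller residual SD, then fewer
variables (parsimony), then lexicographic names — the ordering of the
first two criteria is given, the tie-breaks are ours.  The winner is
refit by `lm()` for full inference.  Diagnostics follow the reported
regimen: VIF (via the inverse correlation matrix), partial correlations
(via the t-statistic identity $r = t/\sqrt{t^2 + df}$), Jarque–Bera and
Lilliefors normality tests and a Wald–Wolfowitz runs test on residual
signs.  Jarque–Bera and the runs test are computed from their standard
closed forms; Lilliefors comes from `nortest`.  A benchmark with all
two-way interactions of the standardized significant main effects
(zero-order Pearson p < 0.05) sits between the linear and neural models.

## The dual-MLP correlation model

Two feed-forward networks are trained jointly on standardized data: the
x-network (tanh hidden layer, default 4 units) maps the selected
predictors to a nonlinear score $u$; the y-network (identity hidden
layer) maps EWL to a score $v$, and is therefore exactly affine — so
$|\mathrm{cor}(u,v)| = |\mathrm{cor}(u,\mathrm{EWL})|$, making the
construction a nonlinear analogue of the multiple correlation
coefficient (a neural form of canonical correlation analysis).  The
training cost is
$$J_m = -\mathrm{cor}(u, v) + \lambda\left[\bar u^2 + \bar v^2 +
  (\mathrm{var}(u) - 1)^2 + (\mathrm{var}(v) - 1)^2\right],$$
the standard penalty construction for the stated zero-mean/unit-variance
constraints; $\lambda$ defaults to 1.  Because the correlation is
invariant to affine rescaling of the scores, the penalties cost nothing
at the optimum, and accepted models meet the constraints to within
|mean| ≤ 0.01, |SD − 1| ≤ 0.05 on their training split.

Choices the source description leaves open, and what this package does:

* **Optimizer.** BFGS (`optim`) with analytic gradients; relative
  function tolerance 1e-6, iteration cap 500.  The tolerance mirrors the
  defaults of mainstream quasi-Newton implementations; runs converge
  well inside the cap.
* **Initialization.** All weights and biases uniform on
  ±0.5/√fan-in, seeded per run.
* **Multi-start protocol.** 200 runs by default; each run draws a fresh
  20% validation split (a fixed shared split is available via
  `fixed_split`), trains on the remainder, and is *rejected* when the
  score correlation on the validation split is strictly lower than on
  the training split.  Among accepted runs, the lowest $J_m$ wins.  The
  sign indeterminacy $(u,v) \to (-u,-v)$ is resolved so that
  $\mathrm{cor}(v, \mathrm{EWL}) \ge 0$.
* **Reported correlation.** The headline `corr_all` is computed on all
  records with the selected run's networks (the convention under which
  the full-cohort model summary with $N$ equal to the whole sample is
  reported); the split-wise `corr_train` / `corr_val` are kept
  alongside.
* **Hidden size.** Default 4 units in both networks (the y-network
  retains 4 units for symmetry even though it collapses to an affine
  map; a 1-unit y-network is an equivalent reduced option).
  `select_hidden_size()` exposes the size-vs-correlation trace and the
  smallest-size-before-diminishing-returns rule.

### Behaviour of the rejection rule — a caveat worth knowing

Maximal-correlation training is optimistic in sample: at n = 500 with 4
hidden units the training-split correlation exceeds the generalization
correlation by roughly 0.05–0.13.  Two consequences, both verified in
the test suite and visible in its output:

1. The strict rejection rule (`corr_val < corr_train`) accepts only a
   small fraction of runs (~4–10%); with small run budgets an entire
   multi-start can be rejected.  `train_multistart()` then errors with
   advice, or falls back to the lowest-$J_m$ run when
   `allow_unaccepted = TRUE` (the fold-wise cross-validation uses this
   fallback, flagged in the training record).
2. At weak planted signal (correlation ≈ 0.4) the runs most likely to
   *pass* the guard are inferior local optima whose training correlation
   is low — the guard then selects against good solutions.  With the
   default 200-run budget enough good runs pass for selection to work;
   with 50 runs recovery at low signal is unreliable.  This is a
   property of the published protocol as described, faithfully
   implemented, not an artifact we chose to engineer away.

## Evaluation layer

* **Binary task.** Positive class = EWL above the first quartile.  ROC
  curves sweep every distinct score cutoff (predict positive when score
  exceeds the cutoff); AUC by the trapezoidal rule (equal to the
  tie-corrected Mann–Whitney statistic, asserted against an exhaustive
  pair-counting oracle), standard error by the Hanley–McNeil asymptotic
  formula (the published table names none), best cutoff by minimal
  Euclidean distance to the (0, 1) corner with ties resolved toward
  higher sensitivity.  Reported percentages are rounded half-up to one
  decimal; raw fractions are retained.
* **Quartile confusion.** Rows = actual quartile, columns = predicted
  quartile, column-normalized.  Predicted quartiles use the predicted
  scores' own thresholds by default (matching a quartile division of the
  model scores); reusing actual-EWL thresholds is supported.
* **Cross-validation.** Repeated (default 100×) random 3-fold splits;
  "homogeneous random subgroups" is implemented as simple random
  near-equal thirds, with optional stratification by actual-EWL quartile
  behind a flag.  Standardization parameters and both sets of quartile
  thresholds are computed on the training folds only and applied to the
  held-out fold — a deliberate strengthening against leakage, since the
  source protocol does not state where thresholds were computed.  Cell
  means ± SEM over repeats summarize prediction value, and the
  below/above-median aggregates sum actual-quartile pairs within a
  predicted-quartile column.
* **Normative comparison.** T scores are rounded half-up to integers and
  binned into <50 / 50–64 / 65–74 / ≥75; the observed class counts are
  tested against the normative distribution (50.00 / 43.32 / 6.06 /
  0.62 percent, shipped as an editable CSV) by the chi-square goodness
  of fit, with adjusted standardized residuals
  $(O - E)/\sqrt{E(1 - p)}$ as the post-hoc per-class test.  No
  multiple-testing correction is applied across scales by default,
  matching per-scale flagging; a Bonferroni option exists.

## Numerical and degenerate-input policy

Zero-variance columns fail standardization unless fold parameters are
supplied; constant score vectors fail quartile division; single-class
label vectors fail ROC construction; empty extreme quartiles fail
centroid computation; perfect collinearity flags infinite VIF rather
than erroring the whole diagnostics table.  Quantiles are type 7
throughout; SDs use the n−1 convention everywhere, including inside the
score-variance penalties.

## Problem sizes used by the shipped analyses and tests

The analysis scripts simulate the full 172-subject cohort with 200
training restarts and 100 CV repeats for the linear model; the dual-MLP
cross-validation uses 30 repeats with 20 restarts per fold, a budget
chosen to keep the stage to a few minutes on one core while leaving the
SEM of each confusion cell below half a percentage point.  The test
suite validates planted-recovery behaviour at n = 500 with 50 restarts
(5 seeds per planted correlation) and the calibration suites at 2000
multinomial replicates, sizes at which the sampling error of each check
sits well inside its stated tolerance.

## Known limitations

The generator's Gaussian copula and exchangeable blocks are a stylized
stand-in for real psychometric covariance; planted-truth recovery does
not imply comparable performance on clinical data.  The dual-MLP model
inherits the published protocol's reliance on a noisy validation
comparison for overfitting control (see the caveat above).  Cohort-
specific fitted quantities of the original study (its coefficients,
thresholds, AUCs) depend on an undeposited data set and are used here
only as exact-arithmetic surfaces, not as reproduction targets.
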