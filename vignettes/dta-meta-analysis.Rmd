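---
title: "Meta-analysis of diagnostic test accuracy with dtameta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of diagnostic test accuracy with dtameta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtameta)
```

## The problem

A diagnostic test accuracy (DTA) meta-analysis asks how well an imaging test
discriminates diseased from non-diseased subjects across a body of published
studies. The motivating application is choline PET/CT in patients with a
biochemical (PSA) relapse of prostate cancer: each study contributes a 2x2
table of true/false positives and negatives against a reference standard,
and many studies additionally report a *detection rate* — the fraction of
scanned patients with a positive scan — stratified by the trigger PSA level
at the time of imaging. dtameta implements the full analysis chain for this
setting: per-study metrics, heterogeneity-gated pooling, a summary ROC
curve, detection-rate pooling by stratum, subgroup comparison, leave-one-out
sensitivity analysis, and a publication-bias test.

## Models and procedures

### Per-study metrics

For a table (tp, fp, fn, tn): sensitivity tp/(tp+fn), specificity
tn/(tn+fp), likelihood ratios LR+ = sens/(1-spec) and LR- = (1-sens)/spec,
and the diagnostic odds ratio DOR = (tp·tn)/(fp·fn) with
SE(ln DOR) = sqrt(1/tp + 1/fp + 1/fn + 1/tn). Any table containing a zero
cell first receives the standard continuity correction — 0.5 added to all
four cells of that study only — so odds-based quantities stay finite for
studies with 100% sensitivity or specificity. The correction is recorded in
a `corrected` flag, and the original integer counts remain recoverable,
because two conventions coexist deliberately: proportion confidence
intervals are Clopper–Pearson exact on the *uncorrected* counts (the
convention of the classical DTA software this package's outputs resemble),
while pooling weights and ratio intervals use logit/log-Wald variances on
the *corrected* cells, which keeps the pooled arithmetic analytic. The
normal quantile is carried internally at full precision (1.959964) so that
rounding never compounds through pooled intervals.

### Pooling and heterogeneity

All pooling is generic inverse variance on a transform scale: logit for
proportions (sensitivity, specificity, detection rates), log for ratios
(LR+, LR-, DOR, odds ratios). The fixed-effect pool uses weights
\(w_i = 1/v_i\); Cochran's \(Q = \sum w_i(\theta_i - \hat\theta_F)^2\) on
\(k-1\) degrees of freedom gives the heterogeneity p-value and
\(I^2 = \max(0, 100\,(Q - df)/Q)\). The random-effects pool is
DerSimonian–Laird: \(\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))\),
re-weighting by \(1/(v_i + \tau^2)\). When \(Q \le k-1\) the estimate
truncates to zero and the random-effects result coincides with the fixed
one exactly — a property the test suite asserts bit-for-bit. No REML or
Paule–Mandel alternatives are offered; DL is the estimator this analysis
family is built on.

Which model an analysis uses is governed by an explicit gate
(`select_model()`), because applied meta-analyses are not consistent about
it: three presets are exposed — `joint` (random if \(I^2 \ge 50\%\) or
heterogeneity p < 0.10; the default), `i2_only` (the \(I^2\) gate alone,
common for odds-ratio pooling), and `p_only` (chi-square p < 0.05). The
thresholds are configurable rather than hard-coded, and detection rates are
always pooled with random effects regardless of preset, reflecting how the
generic inverse-variance approach is used for single proportions in this
literature. Sensitivity and specificity are pooled independently
(univariate); the bivariate Reitsma/HSROC family is a deliberate non-goal.

### Summary ROC, AUC and Q*

Studies use different positivity thresholds, so a single pooled
(sens, spec) pair understates what the test can do. The Moses–Littenberg
construction regresses \(D_i = \mathrm{logit}(TPR_i) - \mathrm{logit}(FPR_i)\)
on \(S_i = \mathrm{logit}(TPR_i) + \mathrm{logit}(FPR_i)\); the fit
\(D = a + bS\) maps back to the curve
\(\mathrm{logit}(TPR) = a/(1-b) + \frac{1+b}{1-b}\,\mathrm{logit}(FPR)\).
The regression is unweighted by default, following the original
recommendation; inverse-variance weighting by \(1/\mathrm{var}(D_i)\) is a
flag, since published analyses rarely state which they used and the two can
differ visibly. The AUC integrates the curve by the trapezoid rule on an
FPR grid of step 0.001 over the full [0, 1] axis with endpoints (0,0) and
(1,1); halving the step moves the AUC by less than 1e-5 (a convergence
guard in the tests), and for a symmetric curve (b = 0, a = ln R) the grid
value agrees with the closed form \(R(R-1-\ln R)/(R-1)^2\) to 1e-4.
Integrating the *extrapolated* curve over all of [0, 1] is itself a choice:
it matches how a single global AUC is reported in this literature, but it
extrapolates beyond the observed FPR window, so `auc_range = "observed"`
reports the partial area over the observed window instead. The Q* index —
the point where sensitivity equals specificity — is \(1/(1+e^{-a/2})\)
regardless of slope, with a delta-method standard error; for a symmetric
curve anchored at a pooled DOR this reduces to `qstar_from_dor()`,
\(1/(1 + DOR^{-1/2})\).

### Second-order analyses

Subgroup comparisons (e.g. 11C- vs 18F-labelled tracer) are two-sided Z
tests on the transform scale, \(z = (\theta_A - \theta_B)/\sqrt{se_A^2 + se_B^2}\).
The comparison is asymptotic in the number of studies per arm; with few
studies the DL standard errors carry estimation noise and the test runs
slightly anticonservative, which is why the size simulations in the test
suite use the generator's default meta-analysis size (29 arms per group).

Leave-one-out sensitivity analysis re-pools each k-1 subset and ranks
datasets by how much their removal changes \(I^2\); the top row flags the
dominant heterogeneity source, mirroring how applied meta-analyses identify
a single outlying study whose exclusion resolves apparent heterogeneity.

Publication bias uses Deeks' test — the appropriate funnel-asymmetry test
for DTA data, where conventional Egger/Begg tests are misleading: weighted
least squares of ln DOR on \(1/\sqrt{ESS}\) with weights equal to the
effective sample size \(ESS = 4 n_1 n_2/(n_1+n_2)\). Inference on the slope
uses the t distribution with k-2 degrees of freedom rather than the normal,
a small-k honesty choice given that odds-ratio analyses in this field can
involve as few as 8 datasets. ESS is computed from the original integer
sample sizes; only the log-DOR uses corrected cells.

## The synthetic-data generators

Study-level supplementary tables are frequently unavailable for published
meta-analyses, so the package ships seeded generators that emulate the
statistical structure of such tables; they are first-class, tested code and
double as the simulation engine for the package's own validation suites.

* `simulate_accuracy()` draws per-study (logit sens, logit spec) from a
  bivariate normal — defaults: 29 arms, mean sensitivity 0.82 and
  specificity 0.92, between-study SD 0.3 on the logit scale, correlation
  -0.3 — then binomial cell counts with arm sizes uniform on 20–150. The
  negative correlation encodes the threshold-driven sens/spec trade-off so
  SROC fitting has signal; set `rho = 0` for univariate experiments.
* `simulate_detection()` models the study-level logit detection rate as
  linear in log trigger PSA, `beta0 + beta1 ln(m) + N(0, tau)` at the
  stratum midpoint m. Defaults beta0 = -0.832, beta1 = 1.757, tau = 0.4,
  6 studies per stratum, n uniform on 30–120. The coefficients were fixed
  once by anchoring the curve to the characteristic published pattern for
  choline PET/CT (rates under 10% below 0.5 ng/ml, around 20% near 1 ng/ml,
  70–90% above 2 ng/ml), with the slope steep enough to reproduce the
  observed jump between the sub-1.5 and over-2 ng/ml strata. Midpoints for
  one-sided strata are half the bound for "<" strata and 1.5x the bound for
  ">" strata. Mixing strata in one pool automatically yields the extreme
  overall heterogeneity (I² above 90%) that overall detection-rate pools
  show in practice.
* `simulate_effects()` draws study log odds ratios around a common truth
  (default ln 1.25, a modest positive PSA effect) with CI bounds
  back-computed from the drawn SE.

All generators are pure functions of their configuration, including the
seed: the global RNG state is saved and restored, and the same config gives
byte-identical output.

What the generators do *not* emulate: verification bias, imperfect
reference standards, correlation between accuracy and detection datasets
from the same article, and any systematic relation between study size and
effect (so they are *unbiased* by construction, which is what the
publication-bias size simulations require). Passing the simulation suites
therefore demonstrates that the estimators recover the truth under the
stated model, not that any particular published dataset was reproduced.

## Numerical and design notes

* Zero-cell correction adds 0.5 to all four cells of the affected study
  only, not to every study; "larger than 9" QUADAS filtering means a score
  of at least 10, with the threshold configurable.
* Pooling requires k ≥ 2, SROC and leave-one-out k ≥ 3; a constant Deeks
  regressor (all studies the same effective size) is flagged degenerate
  with an NA p-value rather than silently dropped.
* Proportion pools back-transform through the inverse logit, so pooled
  points and CI limits always lie strictly inside (0, 1); log-scale pools
  stay positive.
* Multiple arms from one article are distinct rows keyed by
  (study_id, arm) and pool as independent datasets.
* Simulation sizes in the validation suites (200 replicates for parameter
  recovery, 500 for subgroup-test size, 1000 for Deeks-test size, 100 seeds
  for the detection-pattern check) were chosen to keep Monte-Carlo error
  well inside the asserted bands.

## Known limitations

Univariate pooling ignores the sens/spec correlation that bivariate models
exploit; the Moses–Littenberg SROC is descriptive (measurement error in S
is ignored) and is extrapolated beyond the observed FPR range when
`auc_range = "full"`; DL confidence intervals are slightly narrow when k is
small and tau² is large; subgroup Z tests inherit both issues. These are
faithful properties of the classical DTA toolchain this package implements,
not defects to be patched silently.
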