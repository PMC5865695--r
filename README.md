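# dtameta

Meta-analysis of diagnostic test accuracy (DTA) studies in R, built for the
setting where each study reports a 2x2 table (TP/FP/FN/TN) against a
reference standard — the motivating application being choline PET/CT for
detecting recurrent prostate cancer in patients with a rising PSA — and
many studies additionally report a *detection rate* (positive scans /
scanned) stratified by the trigger PSA level.

The package implements the classical univariate DTA toolchain end to end:

* **Per-study metrics** — sensitivity, specificity, PPV/NPV with exact
  Clopper–Pearson intervals; LR+ = sens/(1−spec), LR− = (1−sens)/spec and
  the diagnostic odds ratio DOR = (TP·TN)/(FP·FN) with log-normal Wald
  intervals, SE(ln DOR) = √(1/TP + 1/FP + 1/FN + 1/TN); 0.5 zero-cell
  continuity correction.
* **Pooling** — generic inverse-variance fixed-effect and
  DerSimonian–Laird random-effects pooling on the logit (proportions) or
  log (ratios) scale, with Cochran Q, I² = max(0, 100(Q−df)/Q), τ², and a
  configurable fixed-vs-random heterogeneity gate (I² ≥ 50% and/or
  chi-square p thresholds).
* **Summary ROC** — Moses–Littenberg regression D = a + bS with
  D = logit(TPR) − logit(FPR), S = logit(TPR) + logit(FPR); AUC by
  trapezoid integration of the back-mapped curve; Q* = 1/(1 + e^(−a/2)),
  the sensitivity-equals-specificity point, with delta-method SE.
* **Second-order analyses** — subgroup Z tests on the transform scale,
  leave-one-out sensitivity analysis ranked by ΔI², and Deeks'
  funnel-asymmetry test (WLS of ln DOR on 1/√ESS, weights ESS,
  ESS = 4n₁n₂/(n₁+n₂), t inference on k−2 df).
* **Synthetic data** — seeded generators of accuracy, detection-rate and
  odds-ratio study sets with controllable between-study heterogeneity,
  used both as stand-ins for unavailable study-level supplementary tables
  and as the engine for the package's simulation-based validation.
* **Pipeline** — `run_pipeline()` assembles everything into a report
  bundle and `render_tables()` exports publication-shaped CSV/markdown
  tables plus a full-precision JSON report.

## Worked example

```r
library(dtameta)

acc <- simulate_accuracy(accuracy_sim_config(seed = 42))   # 29 study arms
cfg <- analysis_config(
  accuracy  = acc,
  detection = simulate_detection(detection_sim_config(seed = 42)),
  effect    = simulate_effects(k = 9, seed = 42))
rep <- run_pipeline(cfg)
rep
#> Diagnostic test accuracy meta-analysis report
#>   accuracy: 29 arms; pooled sens 0.835, spec 0.915, DOR 58.60
#>   SROC: AUC 0.9466, Q* 0.8862; Deeks p 0.250
#>   detection: 48 records; pooled rate 0.644 (I2 96.0%)
#>   odds ratio: k = 9; pooled OR 1.339 (fixed-effect)
```

The generator's true values are sensitivity 0.82 and specificity 0.92 with
between-study SD 0.3 on the logit scale; the pooled 0.835/0.915 recover
them within sampling error, and the large I² on the detection pool is the
expected consequence of mixing PSA strata whose true rates range from under
10% to near 90%. Drilling into the pieces:

```r
rep$accuracy$pools$sens
#> Pooled estimate (random-effect, logit scale, k = 29)
#>   point = 0.8355  [95% CI 0.8097, 0.8583]
#> Heterogeneity: Q = 65.41 on 28 df (p = 7.947e-05), I2 = 57.2%, tau2 = 0.1277

rep$sroc
#> Summary ROC (Moses-Littenberg, unweighted fit)
#>   a = 4.1054 (SE 0.2291), b = -0.0571 (SE 0.2043)
#>   AUC = 0.9466, Q* = 0.8862 (SE 0.0116)

rep$deeks
#> Deeks' funnel asymmetry test (k = 29): slope = -9.078, p = 0.2501

render_tables(rep, "report")   # table1/table2 csv+md, sroc_curve.csv,
                               # funnel.csv, loo.csv, report.json
```

A slope near zero with I² ≈ 57% says the studies disagree more than chance
but share no threshold-driven asymmetry; Deeks' p = 0.25 gives no evidence
of small-study effects (the generator plants none).

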