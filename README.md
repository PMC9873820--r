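# ampmilk

Estimation of total daily milk yield from a single morning (AM) or evening
(PM) milking, for twice-daily milked dairy herds recorded under AM-PM
plans. Intended for quantitative geneticists and DHI analysts who build or
evaluate milking-interval correction factors, and for anyone who wants the
whole family of classical and regression estimators behind one interface.

## The models

Let $x_{ij}$ be the weighed yield of cow $i$ at milking $j$ (AM or PM),
$t_{ij}$ its milking interval in hours, and $y_{ij}$ the daily yield. The
package fits, under one front-end:

* **Doubling (M0):** $\hat y = 2x$.
* **Additive correction factors (M1/M2A/M2B):**
  $\hat y = \Delta_{j(k)} + 2x$, with $\Delta_{j(k)}$ the mean AM-PM yield
  difference of the milking-interval class $k$ (raw, factorial, or
  smoothed linearly in the class midpoints). Mirror-class factors sum to
  zero exactly.
* **Linear regression (M3A/M3B):**
  $y = \alpha_j + \beta t + b\,x + \varepsilon$ with free $b$, predicting
  at the continuous interval (M3A) or through the discretized factor table
  $\Delta_{j(k)} = \hat\alpha_j + \hat\beta\,\bar t_{j(k)}$ (M3B). The
  difference per record is exactly the discretization bias
  $\hat\beta\,(t - \bar t_{j(k)})$.
* **Multiplicative correction factors (M4/M5/M6A/M6B):** bulk-ratio
  factors $F_{\mathrm{AM}} = (\mathrm{AMP}+\mathrm{PMP})/\mathrm{AMP}$
  with $1/F_{\mathrm{AM}} + 1/F_{\mathrm{PM}} = 1$ and quadratic-portion
  smoothing (M4); per-class regression through the origin
  $\sum xy/\sum x^2$ with linear reciprocal smoothing (M5); proportion
  regression $x/y = \alpha_j + \beta t$ predicting $x/\hat p(t)$ (M6A) or
  via class factors $1/\hat p(\bar t_{j(k)})$ (M6B).
* **Exponential regression (M7A/M7B):**
  $\log y = \alpha_j + \beta t + b \log x + \varepsilon$, i.e.
  $\hat y = x^{\hat b} e^{\hat\alpha_j + \hat\beta t}$ (M7A), and its
  class-wise factors
  $F_{j(k)} = \rho_{j(k)}\,\bar x^{\hat b - 1} e^{\hat\alpha_j + \hat\beta \bar t_{j(k)}}$
  with the second-order Taylor moment correction $\rho$ (M7B). Rewritten
  as growth, $\hat y = x^{\hat b}(1+r)^{t^*}$ with $r = e - 1 = 1.718$.

A truncated-normal herd simulator on a saturating Michaelis-Menten yield
curve generates reference herds, and a repeated 10-fold cross-validation
benchmark decomposes each model's MSE into variance and squared bias and
reports predictive R² accuracies. See the vignette
(`vignettes/daily-yield-estimation.Rmd`) for the models, identities,
simulator assumptions and the noise-SD calibration.

## Worked example

```r
library(ampmilk)
herd <- simulate_herd(sim_params(n_cows = 3000, seed = 1))

fit <- fit_daily_yield(herd, "M7A")
fit
#> Daily-yield model M7A: exponential regression (continuous interval) (n = 6000 milkings)
#> alpha_am alpha_pm     beta        b
#>   1.5787   1.5783  -0.0298   0.7872

new <- data.frame(cow_id = "new1", session = "AM", interval_h = 10.8,
                  single_yield_kg = 11.2, daily_yield_kg = 11.2)
predict(fit, new)
#> [1] 23.55
```

The AM milking of 11.2 kg after a short 10.8-h interval is scaled up to an
estimated 23.55 kg daily yield -- more than doubling, because the evening
interval of this cow-day is the longer one. A factor table makes the same
logic explicit per interval class:

```r
head(as.data.frame(fit_daily_yield(herd, "M1")$table)[,
  c("session", "class", "midpoint_h", "factor", "n")], 4)
#>   session class midpoint_h factor   n
#> 1      AM     0       8.60   2.93  14
#> 2      AM     1       9.25   2.19  25
#> 3      AM     2       9.75   1.63  64
#> 4      AM     3      10.25   1.57 164
```

(Additive factors in kg: an AM milking in class 3, midpoint 10.25 h, gets
+1.57 kg added to twice its yield.) Benchmarking a few models:

```r
preds <- crossvalidate(herd, methods = c("M0", "M1", "M3A", "M7A"),
                       n_reps = 3, seed = 1)
eval_report(preds)[, c("model", "variance", "bias2", "mse", "acc_rep_mean")]
#>   model variance bias2  mse acc_rep_mean
#> 1    M0 0.000000  6.08 6.08        0.710
#> 2    M1 0.002180  5.24 5.24        0.750
#> 3   M3A 0.000301  4.15 4.15        0.802
#> 4   M7A 0.000315  4.19 4.19        0.800
```

Variance across replicates is near zero for every model (the estimates are
precise); the differences are bias. The doubling estimator is worst; the
interval-using regressions recover about a third of its excess error on
this herd. A full 12-model run with factor tables, curves and report files
is one call: `run_full_experiment(run_config(), "out/")`, or from a shell
via `inst/scripts/ampmilk-cli.R` (subcommands `simulate`, `fit`,
`evaluate`, `experiment`).

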