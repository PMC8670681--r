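# mdqr — minimum-distance quantile regression for spatial panels

`mdqr` estimates conditional quantiles of spatial autoregressive (SAR)
panel data models with individual fixed effects,

    y_it = rho * sum_j w_ij y_jt + X_it' beta + eta_i + e_it,

where the tau-th conditional quantile of `e_it` is zero and `W = (w_ij)` is
a known spatial weight matrix. It is aimed at panel econometricians and
spatial-data analysts who want quantile-level spatial effects — how the
spillover coefficient `rho(tau)` and the covariate effects `beta(tau)` vary
across the outcome distribution — without paying the cost of estimating all
`N` fixed effects in one pooled quantile program.

Three estimators are provided:

* **MDQR** (`fit_mdqr`): per-unit time-series quantile regression of `y` on
  the spatial lag `D_it = sum_j w_ij y_jt`, the covariates and an
  intercept, combined across units by inverse-variance (minimum-distance)
  weighting. Fast, but biased: the spatial lag is endogenous by
  construction.
* **IV-MDQR** (`fit_iv_mdqr`): the main estimator. For each candidate `rho`
  on a grid, each unit's quantile regression of `y - rho*D` on covariates
  plus instruments is fit; the `rho` that drives the instrument coefficient
  to zero is that unit's estimate, and the per-unit estimates are combined
  by minimum distance with sandwich covariances
  `V_i = J_i^{-1} S_i J_i^{-T}` (Powell kernel density at zero,
  Hall–Sheather bandwidth). Confidence intervals come from the
  `sqrt(NT)`-normal limit.
* **IV-FEQR** (`fit_iv_feqr`): the pooled fixed-effects baseline with the
  same grid profiling, solved by a structured interior-point method that
  handles the unit-dummy block in `O(NT)` per grid point.

The package also ships the quantile-regression LP engine itself
(`fit_qr`, a Frisch–Newton interior-point solver written for this package),
spatial-weight construction and validation (`build_block_weights`,
`validate_weights`, dense CSV / MTX readers), a simulator for the standard
homoscedastic and heteroscedastic SAR panel designs (`generate_panel`,
`make_instruments`), a Monte Carlo harness (`mc_scenario`, `run_scenario`,
`tabulate_mc`), a quantile-process sweep with pointwise bands
(`quantile_process`), and a command-line interface
(`inst/cli/mdqr.R`, subcommands `simulate`, `fit`, `mc`, `sweep`).

## Worked example

Simulate a 50-unit, 50-period panel from the block-interaction design
(groups of ten, row-normalized weights) with `rho = 0.5`, `beta = 1`, and
fit the median:

```r
library(mdqr)

w     <- build_block_weights(50)
panel <- generate_panel(n_units = 50, n_periods = 50, tau = 0.5, w = w,
                        rho = 0.5, beta = 1, seed = 42)

fit <- fit_iv_mdqr(panel, w, spec = qr_model_spec(tau = 0.5))
fit
#> IV-MDQR fit at tau = 0.5 (N = 50 units, T = 50)
#>  parameter  estimate     lower     upper
#>        rho 0.5014125 0.4277616 0.5750634
#>      beta1 0.9741775 0.9260804 1.0222747
```

The spatial coefficient is estimated at 0.501 with a 95% interval
[0.428, 0.575] covering the generating value 0.5, and the covariate effect
at 0.974 against a truth of 1. The uninstrumented estimator on the same
panel shows the endogeneity bias the instrument removes:

```r
round(fit_mdqr(panel, w, qr_model_spec(tau = 0.5))$theta_hat, 3)
#>   rho beta1
#> 0.612 0.965
```

`rho` is pushed from 0.5 up to 0.61 — the familiar upward bias from
regressing on one's own neighbours' outcomes. A quantile sweep with
pointwise 95% bands:

```r
quantile_process(panel, w, c(0.25, 0.5, 0.75))
#>   tau parameter estimate lower upper
#>  0.25       rho    0.491 0.417 0.565
#>  0.25     beta1    1.007 0.958 1.056
#>  0.50       rho    0.501 0.428 0.575
#>  0.50     beta1    0.974 0.926 1.022
#>  0.75       rho    0.498 0.427 0.570
#>  0.75     beta1    0.999 0.950 1.048
```

In this symmetric design the effects are flat across quantiles, as they
should be. Real panels are read with `read_panel()` (long CSV: `unit`,
`time`, `y`, `X1..Xp`, optional `omega1..omegaq`) and `read_weights()`
(dense CSV or MatrixMarket).

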