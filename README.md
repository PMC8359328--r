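# dsrt — discretized signed-residual-time models

`dsrt` measures **ability** and **response speed** jointly from timed test
data. Under a signed-residual-time (SRT) scoring rule, an item with deadline
`d` scores `S = (2X - 1)(d - T)`: the time left on the clock is credited for
a correct answer and charged for an incorrect one. Splitting response time
into fast/slow at half the deadline and crossing with accuracy gives a
four-category item score (fast-wrong 0 < slow-wrong 1 < slow-right 2 <
fast-right 3), which the package models with a family of polytomous IRT
models — most importantly the **two-dimensional discretized SRT model**

    Pr(S_i = s | θ1, θ2)  ∝  exp{ s·α_i1·θ1 + 1(s ∈ {0,3})·α_i2·θ2 + β_is }

where θ1 is ability and θ2 is a latent speed that raises the probability of
*fast* outcomes regardless of accuracy. θ2 absorbs person differences in
response caution that would otherwise contaminate ability estimates: the
package's Monte Carlo harness shows the unidimensional model's ability
estimates pick up substantial bias when people differ in speed, while the
two-dimensional model removes most of it at a small variance cost.

The package is for psychometricians and methodologists working with
accuracy + RT data under deadlines: it provides scoring rules, simulators
for every model variant (including the continuous SRT model), marginal
maximum likelihood estimation (EM with Gauss–Hermite quadrature, compiled
E-step), EAP person scoring with model-based reliability, a
positive-manifold misfit diagnostic with a parametric-bootstrap predictive
check, comparison fits of hierarchical and IRTree models, and a full
simulation-study harness.

## Worked example

Simulate a 40-item test taken by 1000 persons whose speed varies
independently of ability, then fit both SRT models:

```r
library(dsrt)

items <- study_item_bank(40, speed_slope = 1)   # five intercept sets, tiled
theta <- draw_latents(1000, rho = 0, seed = 1)  # ability + speed latents
scores <- simulate_scores(items, theta, model = "srt2d", seed = 2)

fit1 <- fit_dsrt(scores, model = "srt1d")
fit2 <- fit_dsrt(scores, model = "srt2d")
fit2
#> <dsrt_fit> srt2d model: 1000 persons x 40 items, 4 categories
#>   logLik -44879.01 | AIC 90160.01 | BIC 91146.47 | 201 parameters
#>   latent correlation rho = -0.007
#>   EM converged in 19 iterations

dplyr::bind_rows(glance(fit1), glance(fit2))
#> # A tibble: 2 x 10
#>   model n_persons n_items n_params  loglik    aic    bic      rho converged n_iter
#>   <chr>     <int>   <int>    <int>   <dbl>  <dbl>  <dbl>    <dbl> <lgl>      <int>
#> 1 srt1d      1000      40      160 -47019. 94357. 95142. NA       TRUE          13
#> 2 srt2d      1000      40      201 -44879. 90160. 91146. -0.00685 TRUE          19
```

The two-dimensional model is decisively preferred (dAIC ~ 4200) and its
ability estimates are closer to the truth, even though the misspecified
unidimensional fit *claims* the higher reliability (0.912 vs 0.887 — it
wrongly counts speed variance as ability information):

```r
eap1 <- eap_scores(scores, fit1)
eap2 <- eap_scores(scores, fit2)
c(rmse_1d = sqrt(mean((eap1$eap_theta1 - theta[, 1])^2)),
  rmse_2d = sqrt(mean((eap2$eap_theta1 - theta[, 1])^2)))
#>   rmse_1d   rmse_2d
#> 0.4061092 0.3389741
```

The misfit the speed dimension repairs is visible *before* fitting it: the
first eigenvalue of the inter-item fast/slow-indicator correlation matrix is
far above anything the unidimensional model can generate:

```r
ppc <- ppc_eigen(fit1, scores, n_rep = 500, seed = 3)
ppc
#> <dsrt_ppc> first-eigenvalue predictive check (indicator, 500 replicates)
#>   observed 7.392 | 95% predictive interval [1.471, 1.715] -> OUTSIDE (misfit flagged)
autoplot(ppc)
```

A full Monte Carlo condition (bias/variance/MSE of ability estimates and EAP
reliability per model, with Monte Carlo standard errors):

```r
cond <- run_condition(n_items = 40, speed_slope = 1, rho = 0,
                      n_reps = 100, models = c("srt1d", "srt2d"), seed = 1)
cond$summary[, c("model", "bias_corrected", "variance", "mse", "reliability")]
mse_reduction(cond)      # headline: % MSE drop from adding the speed dimension
autoplot(cond)           # per-person shrinkage plot
```

`emit_tables()` lays study results out as recovery/reliability tables and
writes CSVs; the thin command-line interface (`inst/cli/dsrt.R`, or
`dsrt_cli()` from R) exposes `discretize`, `simulate`, `fit`, `score`,
`check` and `simstudy` subcommands, each writing a JSON manifest so any
artifact is reproducible from its inputs.

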