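---
title: "Measuring ability and speed with discretized signed-residual-time models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ability and speed with discretized signed-residual-time models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrt)
```

## The measurement problem

Computerized ability tests record not only whether each answer is correct but
also how long it took. The signed residual time (SRT) scoring rule turns both
into a single item score: with a shared item deadline $d$, accuracy
$X \in \{0, 1\}$ and response time $T \in [0, d]$,

$$S = (2X - 1)(d - T),$$

so a fast correct answer earns close to $+d$, a slow answer of either kind
earns close to $0$, and a fast incorrect answer costs close to $-d$. The rule
is *normative*: it is announced to the test takers, who are then expected to
tune their response speed to it. Under the continuous SRT model the joint
density of $(X, T)$ given ability $\theta$ is the truncated exponential
family

$$f(x, t \mid \theta) \propto a\, e^{s a}, \qquad
  a = \alpha(\theta - \delta),$$

normalized over $s \in [-d, d]$; its implied marginal accuracy is the
two-parameter logistic $\Pr(X = 1 \mid \theta) =
\mathrm{logistic}(d \alpha (\theta - \delta))$. (`srt_density()`,
`srt_p_correct()`, `simulate_continuous_srt()`.) Note the normalizing
constant must carry the deadline: we use
$\int_{-d}^{d} a e^{sa} ds = e^{da} - e^{-da}$, which reduces to the familiar
$e^{a} - e^{-a}$ only when $d = 1$; the package verifies by numerical
integration that the density integrates to one for any deadline.

The practical problem this package addresses: people differ in how fast they
respond *for reasons unrelated to ability* (caution, risk seeking). A model
whose only person parameter is ability must then misattribute speed
differences to ability, biasing the estimates. The empirical signature is a
*positive manifold* in response times — large first eigenvalue of the
inter-item RT correlation matrix — which one-parameter-per-person SRT models
cannot generate.

## The discretized model family

Discretizing RT at half the deadline ($T^* = 1$ iff $t < d/2$; the boundary
goes to the slow side) and crossing it with accuracy gives the four-category
score of `assign_scores()`:

| outcome | fast, wrong | slow, wrong | slow, right | fast, right |
|---|---|---|---|---|
| $S$ | 0 | 1 | 2 | 3 |

Half-deadline is the unique split for which the implied score distances
between adjacent outcomes are equal under the continuous rule, so the 0–3
coding stays faithful to it. A three-way split into equal thirds gives the
analogous 0–5 coding (`discretize_rt(..., n_bins = 3)`).

All fitted models are softmax models on this score (categories $s = 0,
\dots, C-1$, $\beta_{i0} \equiv 0$):

* **single-parameter** (`"coomans"`): $\Pr(S_i = s) \propto e^{s(\theta - \delta_i)}$;
* **partial credit** (`"pcm"`): $\propto e^{s\theta + \beta_{is}}$;
* **unidimensional SRT** (`"srt1d"`): $\propto e^{s\alpha_i\theta + \beta_{is}}$;
* **nominal** (`"nrm"`): free category slopes $a_{is}$, one dimension;
* **two-dimensional SRT** (`"srt2d"`):
  $$\Pr(S_i = s \mid \theta_1, \theta_2) \propto
    \exp\{s\,\alpha_{i1}\theta_1 + \mathbb{1}(s \in \{0, 3\})\,
    \alpha_{i2}\theta_2 + \beta_{is}\},$$
  where $\theta_2$ raises the probability of *fast* outcomes (0 and 3)
  regardless of accuracy — a latent speed, interpretable as deviation from
  the scoring-rule-optimal pace.

The two-dimensional model is a multidimensional nominal model with scoring
vectors $c_1 = (0,1,2,3)$ on ability and $c_2 = (1,0,0,1)$ on speed
(`prob_nominal()` exposes the general form). For the six-category
discretization the ability scoring is $c_1 = (0,\dots,5)$; since no canonical
speed scoring exists for that case we default to the symmetric loading
$c_2 = (2,1,0,0,1,2)$ — fastest categories load most — and leave it
user-overridable.

Two comparison models complete the family, both on the same four-category
data split into accuracy and the fast indicator: the **hierarchical model**
(`"hm"`; a 2PL for accuracy on $\theta_1$, a 2PL for the fast indicator on
$\theta_2$) and the **IRTree** model (`"irtree"`; a speed branch followed by
branch-specific accuracy 2PLs, nesting the hierarchical model). The latents
are bivariate standard normal with free correlation $\rho$; means 0 and
variances 1 identify the scale.

Why these models predict no positive manifold on their own: under `"srt1d"`
the fast probability *given a correct response* rises with $\theta$ while the
fast probability *given an incorrect response* falls with it
(`p_fast_given_accuracy()`), so speed indicators correlate positively across
items only through the accuracy channel — conditional on equal accuracy they
correlate positively, on unequal accuracy negatively, and the unconditional
sign is contingent. (This sign statement presumes the items' conditional
fast-probability gaps share a sign, which holds for symmetric intercept sets
like the ones used throughout the study design; the test suite draws from
that class.) A genuine manifold therefore requires the $\theta_2$ dimension.

## Estimation

`fit_dsrt()` maximizes the marginal likelihood: the latents are integrated
out over a Gauss–Hermite product grid (`quad_spec()`, default 21 nodes per
dimension; the invariant floor is 11) and the likelihood is climbed with an
EM algorithm — expected category counts per item and node in the E-step
(compiled code), then per-item damped Newton updates on the working scale
(slopes are log-parameterized, so positivity is structural; working-scale
boxes $\log\alpha \in [-6, 4]$ keep boundary cases such as a true zero speed
slope finite and stable). EM cycles are SQUAREM-accelerated: two EM sweeps
are extrapolated and the extrapolation is kept only when it does not lower
the likelihood, so monotonicity is preserved. Convergence is declared at a
relative log-likelihood change below `1e-6` (at most 500 sweeps); reaching
the cap flags `converged = FALSE` on the result rather than erroring.

A nonzero latent correlation is handled by *reweighting* the fixed grid with
the bivariate-normal density ratio rather than by rotating the nodes. This
keeps the item trace lines independent of $\rho$ and makes the $\rho$ update
an exact one-dimensional maximization of the prior-weight term over the
expected node occupancies — at a modest cost in quadrature efficiency at
large $|\rho|$, which the dense-grid oracle test bounds. Starting values are
slopes 1, intercepts from observed category log-odds, $\rho = 0$; a
`start` argument accepts a previous fit, which shortens the optimization
path (it cannot change the maximum) and is used by the study harness across
replications.

Parameter counts, used in AIC/BIC: `coomans` $K$; `pcm` $3K$; `srt1d` $4K$;
`nrm` $6K$; `srt2d` $5K + 1$; `hm` $4K + 1$; `irtree` $6K + 1$.

Degenerate inputs are refused with named offenders: persons or items with no
observations, and items with empty score categories (for the hierarchical
model the requirement is both accuracy and both speed outcomes; for the
IRTree, observations in every branch). Missing entries simply drop out of
the within-person product.

## Person scoring and reliability

`eap_scores()` returns posterior means and standard deviations of the
latents on the quadrature grid under the fitted population distribution.
EAP estimates shrink toward the population mean — visible as a slope below 1
in the recovery plots and as a nonzero average absolute bias even under the
true model. `eap_reliability()` is the model-based EAP reliability
$\mathrm{var}(\widehat\theta) / (\mathrm{var}(\widehat\theta) +
\overline{\mathrm{PSD}^2})$, the standard signal-to-total-variance form. Note a
*misspecified* unidimensional fit reports a *higher* reliability than the
two-dimensional fit on speed-heterogeneous data — it wrongly counts speed
variance as ability information — so reliability alone must not drive model
choice.

## The simulation study harness

`run_condition()` / `run_study()` reproduce the package's evaluation design:
$N = 1000$ persons, $K \in \{20, 40\}$ items tiling the five intercept sets

```{r}
reference_beta_sets()
```

with ability slope $\alpha_{i1} = 0.5$ throughout and speed slope
$\alpha_{i2} = 0$ (null design) or $1$; the speed design crosses
$\rho \in \{0, .2, .5\}$ (the tabulated grid; it is config-driven). At the
population mean the five sets give score probabilities
(.25,.25,.25,.25), (.1,.4,.4,.1), (.4,.1,.1,.4), (.1,.1,.4,.4),
(.4,.4,.1,.1) — the all-zero set necessarily gives the uniform ¼ vector.
Person latents are drawn **once per condition** and held fixed across
replications, so that per-person bias over replications is well defined
(the harness also offers redrawing per replication). The fixed sample is
standardized to the model's identification constraints — empirical mean 0,
variance 1, correlation exactly $\rho$ — because the fitted scale anchors
itself to the realized sample moments; without this, the sampling wobble of
the sample variance (SD $\sqrt{2/(N-1)} \approx 4.5\%$) acts as a single
random scale factor that coherently shifts every bias and variance summary
(see `?draw_latents`). Seeding is a single
master seed with deterministic per-replication children (`child_seed()`),
so any replication can be re-run in isolation and results are identical for
any parallel worker count.

Reported per model: average absolute per-person bias, average
across-replication variance, MSE (per person these satisfy
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{var}$ exactly), and average EAP
reliability, each with a Monte Carlo standard error. Two estimator details
matter when comparing against references computed from many more
replications:

* **Folded noise in |bias|.** With $R$ replications the per-person bias
  carries sampling noise of variance $\mathrm{var}_p / R$; taking absolute
  values folds that noise upward, noticeably so at $R = 100$. We therefore
  also report `bias_corrected`, which subtracts the estimated sampling
  variance inside the square, $\sqrt{\max(\hat b_p^2 - \hat v_p / R, 0)}$,
  before averaging — the comparable quantity across replication budgets.
* **Persons are the sampling unit.** MC standard errors are person-level
  standard errors of the per-person summaries, so they include both the
  finite replication count and the person draw; the reliability SE adds a
  delta-method person-sampling component $\mathrm{rel}(1 -
  \mathrm{rel})\sqrt{2/(N-1)}$. The headline percent-MSE-reduction
  comparison (`mse_reduction()`) uses the paired per-person MSEs of the two
  models for the same reason.

Problem sizes in the shipped test harness and acceptance script: 100
replications per condition, fits on 21 nodes (one dimension) or 15 nodes per
dimension (two dimensions) with a single finer EAP pass (41 and 31 nodes) for
the person estimates. These were chosen by the convergence checks reported in
the test suite: the finer scoring pass removes the visible quadrature
footprint from the person estimates, while fitting beyond 15 nodes per
dimension left every reported aggregate unchanged to well within one Monte
Carlo standard error.

What the generator does *not* emulate: real response-time data are
continuous, often missing by design (adaptive administration), and items
share content structure; passing tests on this generator shows the
estimation and scoring machinery is correct under the model family, not that
the family fits any particular dataset.

## The positive-manifold diagnostic

`rt_eigen_stat()` computes the first eigenvalue of the pairwise-complete
inter-item correlation matrix of RTs (or of the fast/slow indicators, the
default for discretized data). `ppc_eigen()` simulates `n_rep = 500`
datasets from the fitted model at its point estimates — same persons, items
and missingness template, latents redrawn from the fitted population — and
flags the observed statistic against the replicates' 2.5th–97.5th
percentiles. This parametric bootstrap stands where a fully Bayesian
predictive check would put posterior draws; at these sample sizes parameter
uncertainty is minor and the self-consistency test in the suite confirms
approximately nominal coverage under the true model, with the
1D-fit-to-2D-data case flagged essentially always. Pairwise-complete
correlation matrices need not be positive semi-definite; the statistic
carries a `psd` attribute and the minimum pair overlap (default 30) is
configurable.

## Numerical choices and degenerate cases

* All softmax evaluations subtract the column maximum before
  exponentiation.
* $\theta = \delta$ in the continuous model takes the analytic limit
  (uniform density $1/(2d)$); sampling uses the inverse CDF of the signed
  score with a `log1p`/`expm1` form stable near $a = 0$.
* The discretization boundary is half-open everywhere: a response at
  exactly $d/2$ (or at a third boundary) is in the slower bin.
* A response at exactly the deadline is valid, scores $0$, and lands in the
  slowest bin.
* The $\rho$ update is kept within $(-0.98, 0.98)$; reliability of a
  degenerate constant EAP vector is defined as 0.

## Limitations

The continuous two-dimensional extension is out of scope (the family handles
speed only through discretized RT). No standard errors for item parameters
are provided beyond the information criteria. The three-way-split speed
scoring vector is a convention, not an estimate; sparse high-category data
can make the six-category fit fragile, and the empty-category check refuses
such items rather than merging silently.
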