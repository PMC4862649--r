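---
title: "Multi-uncertainty catch-at-age assessment with model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-uncertainty catch-at-age assessment with model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaaens)
```

## The problem

Most stock assessments condition on a single set of biological
assumptions — one growth curve, one natural mortality schedule, one
assessment model — and report only the estimation uncertainty of that
single fit.  `scaaens` implements a workflow that carries **four**
sources of uncertainty through to the final result:

1. **Process uncertainty** in the von Bertalanffy growth parameters,
   expressed as a t-copula over triangle marginals and propagated
   through length slicing into every age-based quantity.
2. **Process uncertainty** in natural mortality, inherited from the
   growth parameters through a length-based mortality curve.
3. **Model uncertainty**, along two axes: two natural-mortality models
   (a constant rate versus a length-based Gislason curve) crossed with a
   grid of statistical catch-at-age model configurations (3 fishing
   mortality x 3 catchability x 2 recruitment submodels = 18, hence 36
   model variants in total).
4. **Estimation uncertainty**, by resampling each fit's parameters from
   the estimated covariance.

The variants are then *integrated* rather than ranked: unstable variants
are discarded by a bimodality (dip) test on final-year harvest rates,
the survivors are weighted by inverse median GCV, and a single set of
result iterations is drawn across variants in proportion to those
weights.

## Conditioning: growth and natural mortality

Growth uncertainty uses triangle marginals because they impose hard,
interpretable bounds.  For the asymptotic length and growth rate the
bounds sit at $\pm 1.96$ standard deviations around the central value
under a 10% coefficient of variation:

```{r}
triangle_bounds_from_cv(130, 0.10)    # L-infinity (cm)
triangle_bounds_from_cv(0.164, 0.10)  # k (1/yr)
```

$t_0$ uses fixed bounds $[-0.184, 0]$ yr with the centre at their
midpoint, $-0.092$.  The central triangle parameter is treated as the
**mode**; all default marginals are symmetric, where mode and median
coincide, so the distinction only matters for asymmetric user input.

Dependence between the three parameters enters through a t-copula.  Only
the correlation structure of the supplied matrix matters — an unscaled
covariance matrix gives identical draws after rescaling by any positive
factor — so the marginal spreads are controlled solely by the triangles.
The default correlation matrix (`default_growth_correlation()`) encodes
the sign pattern typical of von Bertalanffy fits across demersal stocks:
a strong negative correlation between asymptotic length and growth rate
($-0.7$), a moderate positive one between growth rate and $t_0$
($+0.5$), and a weak negative one between asymptotic length and $t_0$
($-0.2$).  It is a configurable default, not an estimate from any
particular database.  The copula degrees of freedom default to 4 (heavy
enough tails to produce joint extremes; configurable).

Natural mortality offers two models.  The `constant` model fixes
$M = 0.4\,\mathrm{yr}^{-1}$ at every length with no process
uncertainty.  The `gislason` model gives M the length shape
$m(\ell) = k (L_\infty/\ell)^{1.5}$ and rescales each curve so that its
unweighted mean over the 1 cm classes with midpoints in the closed
window 15–60 cm (the most exploited lengths) equals Jensen's level
$1.5k$.  Each growth draw produces its own curve from its own
$(L_\infty, k)$, so mortality uncertainty is perfectly coupled to growth
uncertainty — the same draw index refers to the same state of nature in
every module.

## Length slicing

Deterministic slicing allocates each length class to the age
$\lfloor a(\ell_{mid}) \rfloor$ under the draw's growth curve, clamped
below at age 0; classes at or above the draw's $L_\infty$ go to one past
the oldest finite age and are absorbed by the plusgroup.  Aggregation
uses sums for abundance, abundance-weighted means for mean weight (so
biomass is conserved exactly), and unweighted means for natural
mortality and maturity.  The representative length is the class
midpoint (a lower-bound convention would shift every age boundary by
half a class; midpoints are the neutral choice and match how the
weight–length relation is evaluated).

Each iteration receives its own plusgroup: the smallest age whose
cumulative share of time-averaged catch biomass reaches 95%.  Ages above
it are folded in with abundance weighting, which again preserves
biomass.  Because growth draws differ, plusgroups differ across
iterations — short-lived draws may top out at age 6 while slow-growing,
large-$L_\infty$ draws retain many more ages.

Survey indices are sliced with the *same* growth draws and the stock's
per-iteration plusgroup, so stock and index age classes always agree.

## The catch-at-age estimator

The population model is standard exponential-survival accounting with a
plusgroup; catches follow the Baranov equation
$C = \frac{F}{Z}(1 - e^{-Z})N$ and survey indices
$I = qNe^{-\tau Z}$ at survey timing $\tau$.  Submodels give log F, log
q and log recruitment their shapes:

* **fmodel**: additive age and year factors; a tensor product of cubic
  B-splines over age and year; or a logistic selectivity over age whose
  log plateau follows a year smoother.
* **qmodel** (shared by all surveys in the default grid): an age
  smoother constant in time; additive age and year smoothers; or the
  logistic-by-year form.
* **rmodel**: a year smoother on log recruitment, or free annual
  recruitment shrunk towards a Ricker curve
  $R = \alpha S e^{-\beta S}$ of the previous year's spawning biomass
  with a lognormal penalty of sd 0.10 (the stated "10% cv on the
  parameters" is implemented as a deviation penalty; a prior on
  $(\alpha, \beta)$ alone would leave annual recruitment unconstrained,
  which defeats the submodel's purpose of imposing a stock–recruit
  shape).

Smoother basis dimensions adapt to the data: `min(6, n_ages - 2)` on the
age margin and `min(8, ceiling(n_years/4) + 2)` on the year margin,
floored at 2.  All bases include the intercept, so the columns form a
partition of unity and a constant predictor corresponds to equal
coefficients — which is also how starting values are seeded.

Observations are independent lognormals, one variance per data source
(catch matrix, each index), concentrated out analytically.  Estimation
is quasi-Newton (BFGS) from a deterministic, data-driven start: per-age
total mortality from catch-curve cohort declines, a separable rough F
surface projected onto the fmodel design by least squares, abundance
back-calculated through the Baranov equation, and catchability from
index/abundance ratios.  The optimiser restarts from its own optimum up
to three times (restarting resets the Hessian approximation, which
reliably escapes premature convergence of the quasi-Newton path) and
then polishes with finer finite-difference steps, which matters for
near-noise-free data where the concentrated log-variance surface becomes
extremely steep.  A fit is `converged` when the optimiser reports
success and the observed information is finite and positive definite;
its inverse is the parameter covariance used for estimation-uncertainty
resampling.  Failed fits are recorded and dropped, never fatal.

The GCV score is computed on the catch-at-age matrix only:
$\mathrm{GCV} = n\,\mathrm{RSS}/(n-p)^2$ with $n$ the number of observed
catch cells, RSS the sum of squared log-catch residuals, and $p$ the
count of coefficients entering the catch predictor (fmodel +
recruitment + initial-age parameters; survey-only parameters excluded).
The coefficient count is a declared convention — a smoother's effective
dimension is smaller than its coefficient count, but the same convention
is applied to every variant, and only GCV *ratios* matter for the
weights.

## Filtering and model averaging

Some (assessment x mortality) variants respond to process uncertainty
by splitting their iterations into qualitatively different solution
branches; the fingerprint is a bimodal distribution of final-year
harvest rates (catch biomass / stock biomass).  Hartigan's dip statistic
— the distance from the empirical CDF to the nearest unimodal CDF — is
computed by an exact algorithm (`dip_statistic()`, validated against an
independent brute-force minimiser over unimodal CDFs,
`dip_statistic_brute()`), and calibrated by a bootstrap null of
uniform(0,1) samples of the same size.  The significance level defaults
to 0.05 and the null size to 2000; neither is prescribed by theory, and
both are configurable.  Degenerate samples sit exactly at the lower
bound $1/(2n)$ of the statistic and are never rejected.  Variants with
fewer than 10 successful iterations cannot be tested meaningfully and
are rejected by default (`min_iterations`), or retained untested when
the floor is lowered.

Retained variants are weighted by the inverse of their median GCV,
normalised to sum to one.  Model averaging draws `n_select` iterations
(default: the smallest retained variant's success count, so that no
iteration can be reused): each slot picks a variant with probability
equal to its weight, then an unused iteration uniformly within that
variant.  The two-stage scheme is the literal reading of weighting
variants while treating iterations within a variant as equally likely.

## The synthetic operating model

Because no public data set accompanies the workflow, the package ships
an age-structured operating model whose truth is fully known.  The
default scenario spans 15 years and ages 0–10 with the central growth
curve ($L_\infty = 130$, $k = 0.164$, $t_0 = -0.092$), logistic fishery
selectivity with a rise-then-fall year trend (contrast in F is what
makes total mortality identifiable), lognormal recruitment variation
(sd 0.3), Gislason-shaped true M — so the constant-M assessment branch
is deliberately mis-specified and exercises the model-uncertainty axis —
and three surveys with logistic catchability at timings 0.75, 0.75 and
0.875 of the year (October/October/November).  Observation noise is
lognormal with sd 0.1 on both catch and indices.

Lengths are spread around the mean length-at-age with a normal kernel of
constant cv 0.1, discretised to 1 cm classes (2 cm for surveys) with
exact conservation of totals.  This spread is what makes deterministic
slicing an *approximation*: the generator tells us how much slicing bias
the pipeline must absorb.  What the generator does **not** emulate —
ageing error correlated over time, dome-shaped selectivity, discard
processes, time-varying growth or maturity — bounds what passing tests
can certify about real data.

## Numerical choices and test scales

* The triangle quantile uses the closed-form inverse of the
  piecewise-quadratic CDF; degenerate (zero-width) triangles return the
  point mass.
* The t-copula is sampled by Cholesky factorisation of the correlation
  matrix with a shared chi-square mixing variable; correlation matrices
  must be positive definite (eigenvalue tolerance 1e-12).
* Likelihood evaluations floor the per-source RSS at 1e-10 to keep the
  concentrated log-variance finite on noise-free data.
* The dip statistic searches candidate modes at every data point (where
  an atom of the fitted CDF may absorb the jump) and inside every gap
  (golden-section refinement); the junction between the convex and
  concave branches is enforced exactly, with a bisection fallback for
  the rare candidates where it binds.  Ties collapse into shared jump
  corners.
* Test and acceptance runs use scaled-down problem sizes chosen to probe
  each property at meaningful power: slicing conservation on 50
  randomized fixtures of 60–120 length classes; estimator recovery on a
  12-year, 7-age, 2-survey scenario over 20 seeded replicates; the full
  pipeline comparison on a 10-year, 6-age scenario with 12 process
  iterations and the reduced 2-configuration grid.  These sizes are the
  package's own choices for routine verification; all of them scale up
  by configuration.

## Known limitations

* Slicing is deterministic; a statistical age–length key would propagate
  within-age length overlap instead of hard boundaries.
* The GCV degrees-of-freedom convention counts coefficients, not
  effective dimensions, slightly favouring factor models over smoothers
  of equal coefficient count.
* The logistic fmodel fixes its shape parameters across years.
* Reference points, forecasting and management evaluation are out of
  scope; the output is the integrated estimate of stock status history.

## A worked run

```{r, eval = FALSE}
om <- operating_model(n_years = 10, ages = 0:5,
                      survey_timing = c(0.75, 0.875),
                      survey_a50 = c(1, 0.5), survey_qmax = c(0.1, 0.2))
bundle <- simulate_inputs(om, seed = 1)
config <- read_pipeline_config()
config$n_iterations <- 12
config$scaa$grid <- "reduced"
res <- run_pipeline(bundle$catch, bundle$indices, bundle$maturity, config)
res$filter          # dip-test report per variant
res$weights         # inverse-median-GCV weights
head(res$summary)   # per-year quantile series of the averaged stock
```
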