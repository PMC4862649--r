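# scaaens

Multi-uncertainty statistical catch-at-age stock assessment with model
averaging.

## What it does, and for whom

Stock assessments usually condition on one growth curve, one natural
mortality (M) schedule and one assessment model, and report only the
estimation uncertainty of that single fit. `scaaens` is for assessment
scientists who want the *other* uncertainties in the result too. It:

1. **Conditions** a suite of plausible stock states from length-based
   catch and survey data: von Bertalanffy growth parameters
   (L&infin;, k, t0) are drawn from a t-copula with triangle marginals,
   and two natural-mortality models (a constant 0.4 yr⁻¹ and a
   length-based Gislason curve *m(ℓ) = k(L&infin;/ℓ)^1.5* rescaled so
   its 15–60 cm mean equals Jensen's *1.5k*) are crossed with the growth
   draws. Length data are *sliced* to ages with each draw's growth
   curve, with an automatic per-iteration plusgroup at the age holding
   95% of time-averaged catch biomass.
2. **Estimates** a grid of statistical catch-at-age models — 3 fishing
   mortality × 3 catchability × 2 recruitment submodels = 18
   configurations, hence 36 model variants across the two M models —
   by maximum likelihood (lognormal observation errors, Baranov catch
   equation *C = (F/Z)(1 − e^(−Z))N*), and resamples each fit's
   parameters from its covariance for estimation uncertainty.
3. **Integrates** the variants: unstable variants are rejected by
   Hartigan's dip test for bimodality on final-year harvest rates,
   survivors are weighted by inverse median GCV
   (*GCV = n·RSS/(n − p)²* on the catch matrix only), and a single set
   of result iterations is drawn across variants in proportion to the
   weights.

A fully known age-structured operating model (`operating_model()`,
`simulate_inputs()`) generates synthetic length-based inputs with the
same statistical structure, so every stage is testable without external
data. The dip statistic is implemented exactly (`dip_statistic()`),
with an independent brute-force reference (`dip_statistic_brute()`).

## A worked example

Sample the correlated growth parameters and look at their dependence:

```r
library(scaaens)
ge <- sample_growth_params(default_growth_marginals(),
                           copula_spec(default_growth_correlation()),
                           n = 1000, seed = 1)
ge
#> growth ensemble: 1000 draws (seed 1)
#>       linf         k          t0
#> 1 124.3885 0.1776783 -0.09345193
#> 2 131.8015 0.1724539 -0.13054046
#> 3 123.6270 0.1636622 -0.06220141
#> ...
round(cor(ge$draws, method = "spearman"), 2)
#>       linf     k    t0
#> linf  1.00 -0.67 -0.17
#> k    -0.67  1.00  0.48
#> t0   -0.17  0.48  1.00
```

Every draw lies inside its triangle bounds (104.52–155.48 cm for
L&infin;, 0.132–0.196 yr⁻¹ for k), and the realised rank correlations
track the requested structure. Each draw implies its own age–length
boundaries, e.g. 65 cm falls at age

```r
vb_age_at_length(65, growth_draw(ge, 1))
#> [1] 4.067
```

The dip test flags a two-branch harvest-rate distribution immediately:

```r
dip_test(c(rnorm(250, 0.1, 0.01), rnorm(250, 0.5, 0.01)),
         n_boot = 500, seed = 1)
#> Hartigan dip test: D = 0.21810, p = 0.0000 (n = 500, multimodal)
```

A complete run on synthetic data (see the vignette for the full
walkthrough of every stage):

```r
om <- operating_model(n_years = 10, ages = 0:5,
                      survey_timing = c(0.75, 0.875),
                      survey_a50 = c(1, 0.5), survey_qmax = c(0.1, 0.2))
bundle <- simulate_inputs(om, seed = 101)
config <- read_pipeline_config()
config$n_iterations <- 10; config$seed <- 101
config$scaa$grid <- "reduced"; config$ensemble$n_boot <- 300
res <- run_pipeline(bundle$catch, bundle$indices, bundle$maturity, config)
```

In this run the true terminal-year spawning stock biomass was
7.45e5 and the model-averaged 10–90% band was [6.65e5, 1.07e6] with
median 7.09e5 — the ensemble brackets the truth while mixing both
mortality models and both assessment configurations, which is the point
of averaging instead of picking one "best" model.

A thin command-line wrapper over these functions lives at
`inst/scripts/scaaens-cli.R` (`simulate` and `run-all` subcommands).

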