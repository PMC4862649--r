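# Shared fixtures built in code: small operating models and conditioned
# inputs used across the test files.

table2_marginals <- function() default_growth_marginals()

default_copula <- function(df = 4) copula_spec(default_growth_correlation(), df)

# A small, fast operating model: fewer ages/years than the default
# scenario but the same structure.
small_om <- function(...) {
  args <- utils::modifyList(
    list(n_years = 12, ages = 0:6, survey_timing = c(0.75, 0.875),
         survey_a50 = c(1, 0.5), survey_qmax = c(0.1, 0.2)),
    list(...))
  do.call(operating_model, args)
}

# One iteration of age-based data with noise, for estimator tests.
small_fit_data <- function(seed = 1, ...) {
  om <- small_om(...)
  sim <- simulate_population(om, seed)
  om_scaa_data(sim, seed)
}

reduced_configs <- function(n_surveys = 2, timing = c(0.75, 0.875)) {
  scaa_grid(n_surveys, survey_timing = timing)[c(1, 2)]
}

# Random length-frequency fixtures for conservation properties.
random_length_inputs <- function(seed) {
  set.seed(seed)
  n_len <- sample(60:120, 1)
  lower <- seq_len(n_len)
  n_year <- sample(3:8, 1)
  ab <- matrix(rexp(n_len * n_year, rate = 1 / 50), n_len, n_year)
  zero_rows <- sample(n_len, floor(n_len / 4))
  ab[zero_rows, ] <- 0
  lf <- length_frequency(lower, 1, 2000 + seq_len(n_year), ab)
  growth <- sample_growth_params(table2_marginals(), default_copula(),
                                 n = 3, seed = seed)
  mids <- midpoints(lf)
  m_curve <- build_mortality_ensemble("gislason", mids, growth)
  maturity <- stats::plogis((mids - 45) / 6)
  list(lf = lf, growth = growth, m_curve = m_curve, maturity = maturity,
       wl = weight_length_params())
}
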