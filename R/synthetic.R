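#' Synthetic age-structured operating model
#'
#' A fully known operating model that emulates the statistical structure
#' of length-based stock data: von Bertalanffy growth, logistic fishery
#' selectivity with a smooth year trend, lognormal recruitment
#' variation, length-based natural mortality (Gislason-shaped by
#' default, so a constant-M assessment is deliberately mis-specified),
#' and several survey indices with logistic catchability and lognormal
#' observation noise.  Lengths are spread around the mean length-at-age
#' with a constant coefficient of variation, which is what makes
#' deterministic length slicing an approximation worth testing.
#'
#' @param n_years number of years (default 15).
#' @param ages modelled ages (default `0:10`; the last age is treated as
#'   a plusgroup).
#' @param growth true [growth_params()] (defaults to the central growth
#'   values: Linf 130 cm, k 0.164, t0 -0.092).
#' @param mortality_model true M shape: `"gislason"` (default) or
#'   `"constant"`.
#' @param constant_m_value rate for a constant-M truth.
#' @param f_a50,f_delta logistic selectivity parameters (age at 50%
#'   selection and width).
#' @param f_trend per-year fishing mortality multipliers (length
#'   `n_years`); defaults to a rise-then-fall contrast pattern peaking
#'   at `f_peak`.
#' @param f_peak peak apical F (1/yr) of the default trend.
#' @param r0 average recruitment (thousands).
#' @param r_sigma lognormal sd of recruitment variation.
#' @param length_cv cv of length-at-age spread.
#' @param obs_sigma_catch,obs_sigma_index lognormal observation sd of
#'   the catch-at-age and survey observations.
#' @param survey_timing fractions of the year at which each survey runs.
#' @param survey_a50 per-survey age at 50% catchability.
#' @param survey_qmax per-survey plateau catchability.
#' @param wl a [weight_length_params()].
#' @param mat_l50,mat_slope maturity-ogive parameters (cm).
#' @param fbar_range reference ages for mean F.
#' @return Object of class `operating_model` with derived age schedules
#'   (`mean_length`, `weight`, `maturity`, `m`, `f`).
#' @export
operating_model <- function(n_years = 15, ages = 0:10,
                            growth = growth_params(130, 0.164, -0.092),
                            mortality_model = c("gislason", "constant"),
                            constant_m_value = 0.4,
                            f_a50 = 2, f_delta = 0.5,
                            f_trend = NULL, f_peak = 0.9,
                            r0 = 1e5, r_sigma = 0.3,
                            length_cv = 0.1,
                            obs_sigma_catch = 0.1, obs_sigma_index = 0.1,
                            survey_timing = c(0.75, 0.75, 0.875),
                            survey_a50 = c(1, 2, 0.5),
                            survey_qmax = c(0.1, 0.05, 0.2),
                            wl = weight_length_params(),
                            mat_l50 = 45, mat_slope = 6,
                            fbar_range = c(1, 3)) {
  mortality_model <- match.arg(mortality_model)
  n_surveys <- length(survey_timing)
  stopifnot(length(survey_a50) == n_surveys,
            length(survey_qmax) == n_surveys,
            length_cv > 0, r0 > 0)
  n_a <- length(ages)
  mean_length <- vb_length_at_age(ages + 0.5, growth)
  weight <- weight_at_length(mean_length, wl)
  maturity <- stats::plogis((mean_length - mat_l50) / mat_slope)
  m_age <- if (mortality_model == "constant") {
    rep(constant_m_value, n_a)
  } else {
    grid <- seq(1.5, 128.5, by = 1)
    curve <- jensen_scale(
      mortality_curve(grid, gislason_m(grid, growth), "gislason"),
      k = growth$k)
    stats::approx(grid, curve$m[, 1], xout = pmin(mean_length, max(grid)),
                  rule = 2)$y
  }
  if (is.null(f_trend)) {
    f_trend <- stats::approx(
      x = c(1, round(0.6 * n_years), n_years),
      y = c(0.55, 1, 0.65), xout = seq_len(n_years))$y
  }
  sel <- stats::plogis((ages - f_a50) / f_delta)
  f <- outer(sel, f_peak * f_trend)
  q_age <- lapply(seq_len(n_surveys), function(s)
    survey_qmax[s] * stats::plogis((ages - survey_a50[s]) / 0.7))
  structure(list(
    n_years = n_years, ages = ages, growth = growth,
    mortality_model = mortality_model,
    constant_m_value = constant_m_value,
    mean_length = mean_length, weight = weight, maturity = maturity,
    m = matrix(m_age, n_a, n_years),
    f = f, r0 = r0, r_sigma = r_sigma, length_cv = length_cv,
    obs_sigma_catch = obs_sigma_catch, obs_sigma_index = obs_sigma_index,
    survey_timing = survey_timing, q_age = q_age, wl = wl,
    mat_l50 = mat_l50, mat_slope = mat_slope, fbar_range = fbar_range),
    class = "operating_model")
}

#' @export
print.operating_model <- function(x, ...) {
  cat(sprintf(
    "operating model: ages %d-%d, %d years, '%s' M, %d surveys\n",
    min(x$ages), max(x$ages), x$n_years, x$mortality_model,
    length(x$survey_timing)))
  invisible(x)
}

#' Simulate the true population
#'
#' Runs the operating model forward: lognormal recruitment deviations
#' around `r0`, a near-equilibrium initial age structure, exponential
#' survival with a plusgroup, Baranov catches.
#'
#' @param om an [operating_model()].
#' @param seed integer seed (drives only recruitment deviations).
#' @return List with the true `state` ([project_population()] result),
#'   `catch_n` (true catch-at-age), `weight`, `maturity` matrices, the
#'   recruitment series and the `om`.
#' @export
simulate_population <- function(om, seed = 1) {
  stopifnot(inherits(om, "operating_model"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n_a <- length(om$ages)
  recruits <- om$r0 * exp(stats::rnorm(om$n_years, 0, om$r_sigma))
  z1 <- om$f[, 1] + om$m[, 1]
  surv <- exp(-cumsum(z1[-n_a]))
  n_init <- om$r0 * surv
  n_init[n_a - 1L] <- n_init[n_a - 1L] / (1 - exp(-z1[n_a]))  # plusgroup
  state <- project_population(recruits, n_init, om$f, om$m)
  weight <- matrix(om$weight, n_a, om$n_years)
  maturity <- matrix(om$maturity, n_a, om$n_years)
  list(state = state, catch_n = baranov_catch(state), weight = weight,
       maturity = maturity, recruits = recruits, om = om,
       seed = as.integer(seed))
}

#' True summary series of a simulated population
#'
#' The exact recruitment, SSB, mean F, catch-biomass and harvest-rate
#' series of the operating model, for recovery scoring; identical
#' arithmetic to [summarize_fit()] applied to the true state.
#'
#' @param sim a [simulate_population()] result.
#' @return `data.frame` as from [summarize_fit()].
#' @export
ground_truth <- function(sim) {
  summarize_fit(sim$state, sim$weight, sim$maturity, sim$om$fbar_range,
                ages = sim$om$ages)
}

# Spread an age-indexed matrix over length classes with a normal
# length-at-age kernel discretized to the classes (columns of the
# result follow the input's columns; totals are conserved exactly).
.length_render_matrix <- function(values, om, lower, width) {
  bounds <- c(lower, lower[length(lower)] + width)
  n_a <- nrow(values)
  kern <- vapply(seq_len(n_a), function(a) {
    mu <- om$mean_length[a]
    p <- diff(stats::pnorm(bounds, mean = mu, sd = om$length_cv * mu))
    p / sum(p)
  }, numeric(length(lower)))
  kern %*% values
}

#' Render true catches as a length frequency
#'
#' Each age's catch is spread over the length classes with a normal
#' distribution centred at the mean length-at-age (sd = cv x mean) and
#' discretized to the classes; totals are conserved.
#'
#' @param catch_at_age age x year matrix of catch numbers.
#' @param om the [operating_model()].
#' @param lower lower bounds of the length classes (default 1 cm classes
#'   from 1 to 129 cm).
#' @param width class width (cm).
#' @return A [length_frequency()].
#' @export
render_lengths <- function(catch_at_age, om, lower = 1:129, width = 1) {
  ab <- .length_render_matrix(as.matrix(catch_at_age), om, lower, width)
  length_frequency(lower, width, seq_len(ncol(ab)), ab, unit = "thousands")
}

#' Render survey indices as length frequencies
#'
#' For each survey: index-at-age `q N e^{-timing Z}` with multiplicative
#' lognormal noise, spread over 2 cm length classes.
#'
#' @param sim a [simulate_population()] result.
#' @param seed integer seed for the observation noise.
#' @param lower lower bounds of the survey length classes (default 2 cm
#'   classes from 1 to 127 cm).
#' @param width class width (cm, default 2).
#' @return List of [length_frequency()] objects, one per survey, each
#'   with a `timing` attribute.
#' @export
render_surveys <- function(sim, seed = 1, lower = seq(1, 127, by = 2),
                           width = 2) {
  om <- sim$om
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1L)
  lapply(seq_along(om$survey_timing), function(s) {
    i_age <- om$q_age[[s]] * sim$state$n *
      exp(-om$survey_timing[s] * sim$state$z)
    noise <- matrix(exp(stats::rnorm(length(i_age), 0, om$obs_sigma_index)),
                    nrow(i_age))
    lf <- length_frequency(lower, width, seq_len(ncol(i_age)),
                           .length_render_matrix(i_age * noise, om, lower,
                                                 width),
                           unit = "index")
    attr(lf, "timing") <- om$survey_timing[s]
    lf
  })
}

#' Age-based observations straight from the operating model
#'
#' Catch-at-age and survey-index observations with lognormal noise on
#' the operating model's own age grid, bypassing the length domain.
#' Used to exercise the catch-at-age estimator in isolation from
#' slicing error.
#'
#' @param sim a [simulate_population()] result.
#' @param seed integer seed for the observation noise.
#' @return An [scaa_data()].
#' @export
om_scaa_data <- function(sim, seed = 1) {
  om <- sim$om
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 2L)
  catch_obs <- sim$catch_n *
    matrix(exp(stats::rnorm(length(sim$catch_n), 0, om$obs_sigma_catch)),
           nrow(sim$catch_n))
  surveys <- lapply(seq_along(om$survey_timing), function(s) {
    i_age <- om$q_age[[s]] * sim$state$n *
      exp(-om$survey_timing[s] * sim$state$z)
    noise <- matrix(exp(stats::rnorm(length(i_age), 0, om$obs_sigma_index)),
                    nrow(i_age))
    list(index = i_age * noise, timing = om$survey_timing[s],
         year_idx = seq_len(om$n_years))
  })
  scaa_data(catch_obs, sim$weight, sim$om$m, sim$maturity, surveys)
}

#' Simulate a full length-based input bundle
#'
#' Generates everything the pipeline consumes: a catch length frequency
#' (with lognormal catch observation noise applied at age before length
#' rendering), survey index length frequencies, a maturity-at-length
#' ogive, and the exact ground-truth series.
#'
#' @param om an [operating_model()].
#' @param seed integer seed.
#' @param dir optional directory: when given, all tables are also
#'   written as CSV files ([write_length_table()] and friends).
#' @return List: `catch` (length_frequency), `indices` (list of
#'   length_frequency with timings), `maturity` (data.frame
#'   length_lower, value), `truth` (data.frame), `sim`, `om`, `seed`.
#' @export
simulate_inputs <- function(om, seed = 1, dir = NULL) {
  stopifnot(inherits(om, "operating_model"))
  sim <- simulate_population(om, seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 3L)
  catch_obs <- sim$catch_n *
    matrix(exp(stats::rnorm(length(sim$catch_n), 0, om$obs_sigma_catch)),
           nrow(sim$catch_n))
  catch_lf <- render_lengths(catch_obs, om)
  indices <- render_surveys(sim, seed)
  mids <- midpoints(catch_lf)
  maturity <- data.frame(
    length_lower = catch_lf$lower,
    value = stats::plogis((mids - om$mat_l50) / om$mat_slope))
  truth <- ground_truth(sim)
  out <- list(catch = catch_lf, indices = indices, maturity = maturity,
              truth = truth, sim = sim, om = om, seed = as.integer(seed))
  if (!is.null(dir)) .write_input_bundle(out, dir)
  out
}
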