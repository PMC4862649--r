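#' Condition the candidate stock states
#'
#' Step one of the workflow: sample the growth-parameter ensemble,
#' build the natural-mortality ensembles for each mortality model, and
#' slice the length-based catch and survey data into per-iteration
#' age-based stocks and indices.
#'
#' @param catch_lf catch [length_frequency()].
#' @param indices list of survey [length_frequency()] objects; each may
#'   carry a `timing` attribute (fraction of year, default 0).
#' @param maturity data.frame with `length_lower` and `value` columns on
#'   the catch length grid (e.g. from [prepare_maturity()]).
#' @param config pipeline configuration list (see
#'   [read_pipeline_config()]).
#' @param wl a [weight_length_params()].
#' @return List with `growth` (the shared ensemble) and `stocks`: one
#'   entry per mortality model, each holding `stock` (an `age_stock`)
#'   and `age_indices` (list of `age_index`).
#' @export
condition_stocks <- function(catch_lf, indices, maturity, config,
                             wl = weight_length_params()) {
  g <- config$growth
  marginals <- default_growth_marginals(
    linf_mode = g$linf_median, k_mode = g$k_median,
    cv = g$linf_cv, z = g$z, t0_min = g$t0_min, t0_max = g$t0_max)
  marginals$k <- triangle_marginal(
    triangle_bounds_from_cv(g$k_median, g$k_cv, g$z)[1], g$k_median,
    triangle_bounds_from_cv(g$k_median, g$k_cv, g$z)[2])
  corr <- matrix(unlist(g$correlation), 3, 3)
  cop <- copula_spec(corr, tail_df = g$copula_df)
  growth <- sample_growth_params(marginals, cop, config$n_iterations,
                                 seed = config$seed)
  mids <- midpoints(catch_lf)
  mat_vec <- maturity$value[match(catch_lf$lower, maturity$length_lower)]
  if (anyNA(mat_vec))
    stop("maturity ogive does not cover the catch length grid")
  stocks <- lapply(config$mortality$models, function(mm) {
    m_curve <- build_mortality_ensemble(
      mm, mids, growth,
      constant_value = config$mortality$constant_value,
      jensen_window = config$mortality$jensen_window)
    stock <- slice_stock(catch_lf, wl, m_curve, mat_vec, growth,
                         plusgroup_threshold =
                           config$slicing$plusgroup_threshold)
    pg <- vapply(stock$iterations, `[[`, 1L, "plusgroup")
    age_indices <- lapply(indices, function(ix)
      slice_index(ix, growth, pg, timing = attr(ix, "timing") %||% 0))
    list(mortality_model = mm, stock = stock, age_indices = age_indices)
  })
  names(stocks) <- config$mortality$models
  list(growth = growth, stocks = stocks)
}

#' Fit an assessment grid to a conditioned stock
#'
#' Fits every supplied assessment configuration to every iteration of
#' one conditioned stock, optionally replacing each converged fit's
#' summary by one draw of estimation uncertainty.  Failed iterations
#' are dropped and counted, never fatal.
#'
#' @param stock an `age_stock`.
#' @param age_indices list of `age_index` objects.
#' @param configs list of [scaa_config()] objects.
#' @param mortality_model label stored on the resulting variants.
#' @param est_uncertainty logical: resample one estimation-uncertainty
#'   draw per converged fit (default TRUE).
#' @param seed integer seed (drives the estimation-uncertainty draws).
#' @param control optimiser control passed to [fit_scaa()].
#' @param progress optional function(variant_label, iteration, converged)
#'   called after each fit (used for logging).
#' @return List of `model_variant` objects, one per configuration.
#' @export
assess_grid <- function(stock, age_indices, configs, mortality_model,
                        est_uncertainty = TRUE, seed = 1,
                        control = list(), progress = NULL) {
  lapply(configs, function(cfg) {
    summaries <- list(); gcvs <- c(); ids <- c()
    for (i in seq_len(stock$n_iter)) {
      dat <- scaa_data_from_iteration(stock, age_indices, i)
      fit <- fit_scaa(dat, cfg, control = control)
      ok <- isTRUE(fit$converged) && is.finite(fit$gcv) && fit$gcv > 0
      if (!is.null(progress))
        progress(sprintf("sa%s-%s", cfg$id, mortality_model), i, ok)
      if (!ok) next
      smry <- if (est_uncertainty) {
        draw_seed <- (as.integer(seed) + 7919L * cfg$id + i) %% .Machine$integer.max
        tryCatch(
          sample_estimation_uncertainty(fit, 1, draw_seed)$summaries[[1]],
          error = function(e) fit$summary)
      } else fit$summary
      if (any(!is.finite(smry$harvest_rate))) next
      summaries[[length(summaries) + 1L]] <- smry
      gcvs <- c(gcvs, fit$gcv)
      ids <- c(ids, i)
    }
    model_variant(cfg$id, mortality_model, summaries, gcvs, ids)
  })
}

#' Run the full three-step assessment workflow
#'
#' Conditions the candidate stock states (growth and mortality process
#' and model uncertainty), fits the assessment grid to every iteration
#' of every conditioned stock (model and estimation uncertainty),
#' filters unstable variants with the dip test on final-year harvest
#' rates, weights survivors by inverse median GCV, and model-averages
#' the retained iterations into a single result set.
#'
#' @param catch_lf,indices,maturity,wl as in [condition_stocks()].
#' @param config pipeline configuration (see [read_pipeline_config()]);
#'   `config$scaa$grid` may be `"full"` (18 configurations), `"reduced"`
#'   (a 2 fmodel x 1 qmodel x 1 rmodel subset for fast runs), or a list
#'   of [scaa_config()] objects.
#' @return List: `conditioned`, `variants` (all fitted variants),
#'   `filter` (dip-test report), `weights`, `ensemble`
#'   (an `ensemble_result`), `summary` (quantile series), `log`
#'   (per-fit records).
#' @export
run_pipeline <- function(catch_lf, indices, maturity, config,
                         wl = weight_length_params()) {
  conditioned <- condition_stocks(catch_lf, indices, maturity, config, wl)
  timings <- vapply(indices, function(ix) attr(ix, "timing") %||% 0,
                    numeric(1))
  configs <- .resolve_grid(config$scaa$grid, length(indices), timings,
                           config$scaa$fbar_range)
  log_env <- new.env(); log_env$rows <- list()
  progress <- function(variant, iteration, converged) {
    log_env$rows[[length(log_env$rows) + 1L]] <- data.frame(
      stage = "fit", variant = variant, iteration = iteration,
      converged = converged)
  }
  variants <- list()
  for (mm in names(conditioned$stocks)) {
    st <- conditioned$stocks[[mm]]
    variants <- c(variants, assess_grid(
      st$stock, st$age_indices, configs, mortality_model = mm,
      est_uncertainty = isTRUE(config$scaa$est_uncertainty),
      seed = config$seed,
      control = list(maxit = config$scaa$maxit),
      progress = progress))
  }
  filt <- filter_variants(variants,
                          alpha = config$ensemble$alpha,
                          n_boot = config$ensemble$n_boot,
                          seed = config$seed,
                          min_iterations = config$ensemble$min_iterations)
  if (!length(filt$retained))
    stop("pipeline error: all model variants were rejected; ",
         "see the rejection report (dip test / insufficient iterations)")
  weights <- gcv_weights(filt$retained)
  ens <- model_average(filt$retained, weights,
                       n_select = config$ensemble$n_select,
                       seed = config$seed)
  smry <- summarize_ensemble(ens, quantiles = config$ensemble$quantiles)
  list(conditioned = conditioned, variants = variants,
       filter = filt$report, retained = filt$retained,
       weights = weights, ensemble = ens, summary = smry,
       log = do.call(rbind, log_env$rows), config = config)
}

.resolve_grid <- function(grid, n_surveys, survey_timing, fbar_range) {
  if (is.list(grid)) return(grid)
  if (identical(grid, "full"))
    return(scaa_grid(n_surveys, fbar_range, survey_timing))
  if (identical(grid, "reduced")) {
    full <- scaa_grid(n_surveys, fbar_range, survey_timing)
    # age+year factors and tensor-spline fmodels with the age-smoother
    # qmodel and year-smoother rmodel
    return(full[c(1, 2)])
  }
  stop("unknown grid specification")
}

#' Write the variant report table
#'
#' Tabular rejection/weight report mirroring the assessment-grid layout:
#' one row per variant with its success count, dip-test decision, median
#' GCV and (for retained variants) model-averaging weight.
#'
#' @param variants all fitted variants.
#' @param report the dip-test report from [filter_variants()].
#' @param weights weights of the retained variants.
#' @param path optional CSV path.
#' @return The report data.frame, invisibly if written.
#' @export
variant_report <- function(variants, report, weights, path = NULL) {
  report$median_gcv <- vapply(variants, function(v)
    if (length(v$gcv)) stats::median(v$gcv) else NA_real_, numeric(1))
  report$weight <- 0
  report$weight[!report$rejected] <- weights
  if (!is.null(path)) {
    utils::write.csv(report, path, row.names = FALSE)
    return(invisible(report))
  }
  report
}
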