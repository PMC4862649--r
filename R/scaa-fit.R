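#' Data bundle for a single catch-at-age fit
#'
#' One iteration's age-based observations: catch numbers, mean weight,
#' natural mortality and maturity matrices over a common age x year grid,
#' plus one or more survey indices.
#'
#' @param catch_n,weight,m,maturity age x year matrices (ages `0:A`).
#' @param surveys list of surveys, each a list with `index` (age x year
#'   matrix over the survey's years), `timing` in `[0, 1)` and
#'   `year_idx` (columns of the stock years covered).
#' @return Object of class `scaa_data`.
#' @export
scaa_data <- function(catch_n, weight, m, maturity, surveys = list()) {
  catch_n <- as.matrix(catch_n)
  dims <- dim(catch_n)
  stopifnot(all(dim(weight) == dims), all(dim(m) == dims),
            all(dim(maturity) == dims))
  for (s in surveys) {
    stopifnot(nrow(s$index) == dims[1],
              length(s$year_idx) == ncol(s$index),
              s$timing >= 0, s$timing < 1)
  }
  structure(list(catch_n = catch_n, weight = weight, m = m,
                 maturity = maturity, surveys = surveys),
            class = "scaa_data")
}

#' Assemble fit data from sliced stock and indices
#'
#' @param stock an `age_stock` from [slice_stock()].
#' @param indices list of `age_index` objects from [slice_index()].
#' @param i iteration number.
#' @return An [scaa_data()] object for iteration `i`.
#' @export
scaa_data_from_iteration <- function(stock, indices, i) {
  it <- stock$iterations[[i]]
  surveys <- lapply(indices, function(ix) {
    list(index = ix$iterations[[i]], timing = ix$timing,
         year_idx = match(ix$years, stock$years))
  })
  scaa_data(it$catch_n, it$weight, it$m, it$maturity, surveys)
}

# Parameter bookkeeping + likelihood closure for one (data, config) pair.
# theta layout: [fmodel | qmodel_1..S | rmodel | log n_init (ages 2..A)].
.make_scaa_model <- function(data, config) {
  n_a <- nrow(data$catch_n); n_y <- ncol(data$catch_n)
  ages <- seq_len(n_a) - 1L
  years <- seq_len(n_y)
  fdes <- build_design(config$fmodel, ages, years)
  specs <- config$qmodels
  if (length(specs) == 1L && length(data$surveys) > 1L)
    specs <- rep(specs, length(data$surveys))
  if (length(specs) != length(data$surveys))
    stop("need one qmodel per survey")
  qdes <- lapply(specs, build_design, ages = ages, years = years)
  rdes <- build_design(config$rmodel, ages, years)

  npf <- fdes$npar
  npq <- vapply(qdes, `[[`, 0L, "npar")
  npr <- rdes$npar
  npn <- n_a - 1L
  npar <- npf + sum(npq) + npr + npn
  idx_f <- seq_len(npf)
  idx_q <- vector("list", length(qdes))
  off <- npf
  for (s in seq_along(qdes)) {
    idx_q[[s]] <- off + seq_len(npq[s])
    off <- off + npq[s]
  }
  idx_r <- off + seq_len(npr)
  idx_n <- off + npr + seq_len(npn)

  catch_pos <- data$catch_n > 0
  n_catch <- sum(catch_pos)
  log_cobs <- log(data$catch_n[catch_pos])
  surv_pos <- lapply(data$surveys, function(s) s$index > 0)
  log_iobs <- lapply(seq_along(data$surveys), function(s)
    log(data$surveys[[s]]$index[surv_pos[[s]]]))

  ricker <- config$rmodel$form == "ricker"
  sigma_r <- 0.10   # cv of the Ricker recruitment penalty

  decode <- function(theta) {
    logF <- fdes$predict(theta[idx_f])
    if (ricker) {
      th_r <- theta[idx_r]
      logR <- th_r[seq_len(n_y)]
      log_alpha <- th_r[n_y + 1L]
      log_beta <- th_r[n_y + 2L]
    } else {
      logR <- rdes$predict(theta[idx_r])
      log_alpha <- log_beta <- NA_real_
    }
    state <- project_population(exp(logR), exp(theta[idx_n]),
                                exp(logF), data$m)
    q <- lapply(seq_along(qdes), function(s)
      exp(qdes[[s]]$predict(theta[idx_q[[s]]])))
    list(state = state, q = q, logR = logR,
         log_alpha = log_alpha, log_beta = log_beta)
  }

  nll <- function(theta) {
    if (any(!is.finite(theta)) || max(abs(theta)) > 50) return(1e10)
    dec <- decode(theta)
    state <- dec$state
    chat <- baranov_catch(state)
    if (any(!is.finite(chat[catch_pos])) || any(chat[catch_pos] <= 0))
      return(1e10)
    rss_c <- sum((log_cobs - log(chat[catch_pos]))^2)
    val <- n_catch / 2 * log((rss_c + 1e-10) / n_catch)
    for (s in seq_along(data$surveys)) {
      sv <- data$surveys[[s]]
      ihat <- (dec$q[[s]] * state$n * exp(-sv$timing * state$z))[, sv$year_idx,
                                                                 drop = FALSE]
      io <- ihat[surv_pos[[s]]]
      if (any(!is.finite(io)) || any(io <= 0)) return(1e10)
      rss_s <- sum((log_iobs[[s]] - log(io))^2)
      ns <- length(io)
      val <- val + ns / 2 * log((rss_s + 1e-10) / ns)
    }
    if (ricker) {
      ssb <- colSums(state$n * data$weight * data$maturity)
      if (any(ssb <= 0)) return(1e10)
      mu <- dec$log_alpha + log(ssb[-n_y]) - exp(dec$log_beta) * ssb[-n_y]
      val <- val + sum((dec$logR[-1] - mu)^2) / (2 * sigma_r^2)
    }
    if (!is.finite(val)) return(1e10)
    val
  }

  list(nll = nll, decode = decode, npar = npar,
       idx = list(f = idx_f, q = idx_q, r = idx_r, n = idx_n),
       designs = list(f = fdes, q = qdes, r = rdes),
       n_catch = n_catch, catch_pos = catch_pos,
       p_catch = npf + npr + npn, n_a = n_a, n_y = n_y,
       ricker = ricker)
}

# Deterministic data-driven starting values: per-age total mortality
# from catch-curve cohort declines, a separable rough F surface (age
# profile x normalised catch trend) projected onto the fmodel design,
# abundance back-calculated through the Baranov equation, catchability
# from index/abundance ratios.
.init_theta <- function(data, model, config) {
  n_a <- model$n_a; n_y <- model$n_y
  C <- data$catch_n
  # per-age cohort decline Z estimates
  z_age <- rep(NA_real_, n_a)
  if (n_a > 2 && n_y > 1) {
    for (a in seq_len(n_a - 2L)) {
      r <- c()
      for (y in seq_len(n_y - 1L)) {
        if (C[a + 1L, y] > 0 && C[a + 2L, y + 1L] > 0)
          r <- c(r, log(C[a + 1L, y] / C[a + 2L, y + 1L]))
      }
      if (length(r)) z_age[a + 1L] <- stats::median(r)
    }
  }
  z_fallback <- if (all(is.na(z_age))) 0.7 else stats::median(z_age,
                                                              na.rm = TRUE)
  z_age[is.na(z_age)] <- z_fallback
  z_age[1] <- z_age[2]            # recruit age has no decline estimate
  z_age <- pmin(pmax(z_age, 0.15), 2.5)
  f_age <- pmin(pmax(z_age - rowMeans(data$m), 0.05), 2)
  tot <- colSums(C)
  u_y <- pmin(pmax(tot / mean(tot[tot > 0]), 0.3), 3)
  u_y[tot == 0] <- 1
  f0_mat <- pmin(pmax(outer(f_age, u_y), 0.01), 3)
  z_mat <- f0_mat + data$m
  n0 <- C * z_mat / (f0_mat * (1 - exp(-z_mat)))
  floor_n <- max(n0) * 1e-6 + 1e-9
  n0 <- pmax(n0, floor_n)

  theta <- numeric(model$npar)
  des <- model$designs
  theta[model$idx$f] <- .start_design(des$f, log(f0_mat), n_a)
  for (s in seq_along(des$q)) {
    sv <- data$surveys[[s]]
    nh <- (n0 * exp(-sv$timing * z_mat))[, sv$year_idx, drop = FALSE]
    pos <- sv$index > 0 & nh > 0
    q0 <- if (any(pos)) stats::median(log(sv$index[pos]) - log(nh[pos])) else 0
    theta[model$idx$q[[s]]] <- .start_linear(des$q[[s]], q0, n_a)
  }
  log_r0 <- log(pmax(n0[1, ], floor_n))
  if (model$ricker) {
    ssb0 <- pmax(colSums(n0 * data$weight * data$maturity), 1e-9)
    beta0 <- 1 / (2 * mean(ssb0))
    alpha0 <- mean(log_r0[-1] - log(ssb0[-n_y]) + beta0 * ssb0[-n_y])
    theta[model$idx$r] <- c(log_r0, alpha0, log(beta0))
  } else if (!is.null(des$r$basis)) {
    theta[model$idx$r] <- stats::lsfit(des$r$basis, log_r0,
                                       intercept = FALSE)$coefficients
  } else {
    theta[model$idx$r] <- .start_linear(des$r, mean(log_r0), n_a)
  }
  theta[model$idx$n] <- log(pmax(n0[-1, 1], floor_n))
  theta
}

# Project a rough log-predictor matrix onto a design; falls back to the
# constant start for nonlinear forms.
.start_design <- function(design, log_mat, n_a) {
  if (!is.null(design$X)) {
    fit <- stats::lsfit(design$X, as.vector(log_mat), intercept = FALSE)
    cf <- fit$coefficients
    cf[!is.finite(cf)] <- 0
    return(cf)
  }
  .start_linear(design, stats::median(log_mat), n_a)
}

# Starting coefficients producing an approximately constant predictor.
.start_linear <- function(design, const, n_a) {
  if (design$form == "logistic_age_by_year_smoother")
    return(c((n_a - 1) / 3, 0, rep(const, design$npar - 2L)))
  if (design$form == "age_and_year_smoothers") {
    # only the age basis (a partition of unity) carries the constant
    k <- design$n_age_cols
    return(c(rep(const, k), rep(0, design$npar - k)))
  }
  if (design$form == "age_year_factors")
    return(c(const, rep(0, design$npar - 1L)))
  rep(const, design$npar)  # partition-of-unity spline bases
}

#' Negative log-likelihood of a catch-at-age model
#'
#' Independent lognormal observation errors for the catch-at-age matrix
#' and each survey index, one observation variance per data source
#' concentrated out analytically, plus (for the Ricker rmodel) a
#' lognormal penalty with sd 0.10 shrinking annual recruitment towards
#' the Ricker expectation `R = alpha S exp(-beta S)` of the previous
#' year's spawning biomass.
#'
#' @param theta parameter vector (see [fit_scaa()] for the layout).
#' @param data an [scaa_data()].
#' @param config an [scaa_config()].
#' @return Scalar negative log-likelihood (up to additive constants);
#'   non-finite predictions surface as a large finite value so that
#'   optimisers can retreat.
#' @export
negative_log_likelihood <- function(theta, data, config) {
  .make_scaa_model(data, config)$nll(theta)
}

#' Fit a statistical catch-at-age model
#'
#' Maximum-likelihood fit of the configured submodels to one iteration's
#' age-based data.  Optimisation is quasi-Newton (BFGS) from a
#' deterministic data-driven start; the parameter covariance is the
#' inverse observed information at the optimum.  Failed fits are
#' reported through `converged = FALSE`, never raised as errors.
#'
#' @param data an [scaa_data()].
#' @param config an [scaa_config()].
#' @param control optional list: `maxit` (default 400), `reltol`
#'   (default 1e-10).
#' @return Object of class `scaa_fit`: `theta_hat`, `covariance`,
#'   `loglik`, `gcv`, `converged`, `state`, `q_hat`, `summary` (the
#'   [summarize_fit()] series) and bookkeeping used by
#'   [sample_estimation_uncertainty()].
#' @export
fit_scaa <- function(data, config, control = list()) {
  stopifnot(inherits(data, "scaa_data"), inherits(config, "scaa_config"))
  model <- .make_scaa_model(data, config)
  theta0 <- .init_theta(data, model, config)
  maxit <- control$maxit %||% 400L
  reltol <- control$reltol %||% 1e-10

  opt <- tryCatch({
    o <- stats::optim(theta0, model$nll, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
    # restarting resets the Hessian approximation, which often escapes
    # premature convergence of the quasi-Newton path
    for (r in 1:3) {
      o2 <- stats::optim(o$par, model$nll, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
      improved <- o$value - o2$value
      if (o2$value <= o$value) o <- o2
      if (improved < 0.1) break
    }
    # near-zero-residual fits need finer finite-difference steps: the
    # concentrated log-variance surface steepens as the RSS shrinks
    for (nd in c(1e-5, 1e-6)) {
      o2 <- stats::optim(o$par, model$nll, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol,
                                        ndeps = rep(nd, length(o$par))))
      improved <- o$value - o2$value
      if (o2$value <= o$value) o <- o2
      if (improved < 0.1) break
    }
    o
  }, error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(converged = FALSE, reason = "optimizer error",
                          config = config),
                     class = "scaa_fit"))
  }
  theta_hat <- opt$par
  hess <- tryCatch(stats::optimHess(theta_hat, model$nll),
                   error = function(e) NULL)
  covariance <- NULL
  pd <- FALSE
  if (!is.null(hess) && all(is.finite(hess))) {
    ch <- tryCatch(chol(hess), error = function(e) NULL)
    if (!is.null(ch)) {
      covariance <- chol2inv(ch)
      pd <- all(is.finite(covariance))
    }
  }
  converged <- (opt$convergence == 0L) && pd && opt$value < 1e9

  dec <- model$decode(theta_hat)
  chat <- baranov_catch(dec$state)
  rss_c <- sum((log(data$catch_n[model$catch_pos]) -
                  log(chat[model$catch_pos]))^2)
  n_c <- model$n_catch
  p_c <- model$p_catch
  gcv <- if (p_c < n_c) n_c * rss_c / (n_c - p_c)^2 else NA_real_
  summary <- summarize_fit(dec$state, data$weight, data$maturity,
                           config$fbar_range)
  structure(list(
    theta_hat = theta_hat, covariance = covariance,
    loglik = -opt$value, gcv = gcv, converged = converged,
    state = dec$state, q_hat = dec$q, summary = summary,
    rss_catch = rss_c, n_catch = n_c, p_catch = p_c,
    model = model, data = data, config = config,
    counts = opt$counts), class = "scaa_fit")
}

#' @export
print.scaa_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("SCAA fit: NOT converged",
        if (!is.null(x$reason)) paste0(" (", x$reason, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("SCAA fit: %d parameters, loglik %.3f, GCV %.4g\n",
              length(x$theta_hat), x$loglik, x$gcv))
  invisible(x)
}

#' Generalised cross-validation score of a fit
#'
#' `GCV = n RSS / (n - p)^2` computed on the catch-at-age matrix only:
#' `n` is the number of observed catch cells, `RSS` the sum of squared
#' log-catch residuals and `p` the number of coefficients entering the
#' catch predictor (fmodel + recruitment + initial-age parameters;
#' survey-only parameters are excluded).
#'
#' @param fit an `scaa_fit`.
#' @return Positive scalar.
#' @export
compute_gcv <- function(fit) {
  stopifnot(inherits(fit, "scaa_fit"))
  if (!isTRUE(fit$converged) && is.null(fit$rss_catch))
    stop("GCV is only defined for completed fits")
  if (fit$p_catch >= fit$n_catch)
    stop("effective parameters must be fewer than catch observations")
  fit$n_catch * fit$rss_catch / (fit$n_catch - fit$p_catch)^2
}

#' Resample estimation uncertainty from a fit
#'
#' Draws parameter vectors from the multivariate normal centred at the
#' maximum-likelihood estimate with the fit's covariance, and maps each
#' draw to its implied population state and summary series.
#'
#' @param fit a converged `scaa_fit`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return List with `draws` (n x p matrix) and `summaries` (list of
#'   [summarize_fit()] data frames, one per draw).
#' @export
sample_estimation_uncertainty <- function(fit, n, seed) {
  stopifnot(inherits(fit, "scaa_fit"))
  if (!isTRUE(fit$converged))
    stop("cannot resample from a non-converged fit")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n, mu = fit$theta_hat, Sigma = fit$covariance)
  draws <- matrix(draws, nrow = n)
  summaries <- lapply(seq_len(n), function(i) {
    dec <- fit$model$decode(draws[i, ])
    summarize_fit(dec$state, fit$data$weight, fit$data$maturity,
                  fit$config$fbar_range)
  })
  list(draws = draws, summaries = summaries)
}
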