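test_that("design matrices have the documented structure", {
  ages <- 0:2; years <- 1:4
  fac <- build_design(submodel_spec("fmodel", "age_year_factors"),
                      ages, years)
  expect_equal(fac$npar, (3 - 1) + (4 - 1) + 1)
  # additive factor predictor: cell (a, y) = intercept + age_a + year_y
  theta <- c(0.5, 1, 2, 0.1, 0.2, 0.3)
  pred <- fac$predict(theta)
  expect_equal(pred[1, 1], 0.5)
  expect_equal(pred[3, 4], 0.5 + 2 + 0.3)
  expect_equal(pred[2, 3], pred[2, 1] + (pred[1, 3] - pred[1, 1]))

  ys <- build_design(submodel_spec("qmodel", "age_and_year_smoothers",
                                   df = list(age = 3, year = 3)),
                     0:5, 1:10)
  expect_equal(ys$npar, 3 + 2)

  yr <- build_design(submodel_spec("fmodel", "tensor_spline",
                                   df = list(age = 3, year = 4)),
                     0:5, 1:10)
  expect_equal(yr$npar, 12)
  # tensor rows equal the pointwise product of the marginal bases
  Ba <- scaaens:::.bspline_basis(0:5, 3)
  By <- scaaens:::.bspline_basis(1:10, 4)
  theta <- rnorm(12)
  pred <- yr$predict(theta)
  for (cell in list(c(1, 1), c(3, 7), c(6, 10))) {
    direct <- sum(outer(By[cell[2], ], Ba[cell[1], ]) *
                    matrix(theta, 4, 3, byrow = TRUE))
    expect_equal(pred[cell[1], cell[2]], direct, tolerance = 1e-12)
  }

  rsm <- build_design(submodel_spec("rmodel", "year_smoother",
                                    df = list(year = 3)),
                      0:5, 1:10)
  expect_equal(rsm$npar, 3L)
  expect_length(rsm$predict(c(1, 2, 3)), 10L)

  expect_error(submodel_spec("fmodel", "age_smoother"))
  expect_error(submodel_spec("rmodel", "tensor_spline"))
  expect_error(build_design(
    submodel_spec("qmodel", "age_smoother", df = list(age = 10)),
    0:3, 1:10), "df exceeds")
})

test_that("population projection follows survival with a plusgroup", {
  # no mortality: cohorts persist along diagonals
  f <- matrix(0, 3, 4); m <- matrix(0, 3, 4)
  st <- project_population(rep(7, 4), c(3, 5), f, m)
  expect_equal(st$n[2, 2], 7)
  expect_equal(st$n[3, 3], 7 + 5 + 3)  # plusgroup accumulates

  # hand recursion for 2 ages x 2 years with z = 0.5
  f2 <- matrix(0.2, 2, 2); m2 <- matrix(0.3, 2, 2)
  st2 <- project_population(c(10, 12), 4, f2, m2)
  expect_equal(st2$n[2, 2], 10 * exp(-0.5) + 4 * exp(-0.5),
               tolerance = 1e-12)

  # single age class: geometric decay plus recruitment inflow
  st1 <- project_population(c(5, 5, 5), numeric(0),
                            matrix(0.1, 1, 3), matrix(0.4, 1, 3))
  expect_equal(st1$n[1, 2], 5 + 5 * exp(-0.5), tolerance = 1e-12)
  expect_error(project_population(c(-1, 1), 1, f2, m2), "non-negative")
})

test_that("Baranov catch and survey predictions are exact", {
  n <- matrix(100, 1, 1)
  st <- list(n = n, f = matrix(log(2), 1, 1), m = matrix(0, 1, 1),
             z = matrix(log(2), 1, 1))
  expect_equal(baranov_catch(st)[1, 1], 50)
  st2 <- list(n = n, f = matrix(0.2, 1, 1), m = matrix(0.4, 1, 1),
              z = matrix(0.6, 1, 1))
  expect_equal(baranov_catch(st2)[1, 1],
               0.2 / 0.6 * (1 - exp(-0.6)) * 100, tolerance = 1e-12)
  expect_equal(baranov_catch(st2)[1, 1], 15.0396, tolerance = 1e-4)
  st0 <- list(n = n, f = matrix(0, 1, 1), m = matrix(0.4, 1, 1),
              z = matrix(0.4, 1, 1))
  expect_equal(baranov_catch(st0)[1, 1], 0)
  expect_equal(predict_index(st2, matrix(0.1, 1, 1), timing = 0.875)[1, 1],
               0.1 * 100 * exp(-0.875 * 0.6), tolerance = 1e-12)
  expect_equal(predict_index(st2, matrix(1, 1, 1), timing = 0)[1, 1], 100)
})

test_that("summary series compute SSB, Fbar and harvest rate", {
  n <- matrix(c(100, 50), 2, 1)
  f <- matrix(c(0.1, 0.3), 2, 1); m <- matrix(0.2, 2, 1)
  st <- list(n = n, f = f, m = m, z = f + m)
  wt <- matrix(c(1, 2), 2, 1); mat <- matrix(c(0, 1), 2, 1)
  s <- summarize_fit(st, wt, mat, fbar_range = c(0, 1), ages = 0:1)
  expect_equal(s$ssb, 100 * 1 * 0 + 50 * 2 * 1)
  expect_equal(s$fbar, 0.2)
  expect_equal(s$recruitment, 100)
  cb <- sum(baranov_catch(st) * wt)
  expect_equal(s$catch, cb)
  expect_equal(s$harvest_rate, cb / (100 * 1 + 50 * 2))
  s0 <- summarize_fit(st, wt, matrix(0, 2, 1), fbar_range = c(0, 1),
                      ages = 0:1)
  expect_equal(s0$ssb, 0)
})

test_that("likelihood is scale invariant and minimal at the generator", {
  dat <- small_fit_data(seed = 2)
  cfg <- reduced_configs()[[2]]
  model <- scaaens:::.make_scaa_model(dat, cfg)
  th <- scaaens:::.init_theta(dat, model, cfg)
  # doubling observations and predictions cancels in log-ratio residuals:
  # shift all log-scale level parameters and observations consistently
  v1 <- model$nll(th)
  dat2 <- dat
  dat2$catch_n <- dat$catch_n * 2
  for (s in seq_along(dat2$surveys))
    dat2$surveys[[s]]$index <- dat$surveys[[s]]$index * 2
  model2 <- scaaens:::.make_scaa_model(dat2, cfg)
  th2 <- th
  # year-smoother coefficients form a partition of unity, so a uniform
  # shift moves log R (and hence N, catches and indices) by log 2,
  # matching the doubled observations; all log-scale residuals cancel
  th2[model$idx$r] <- th[model$idx$r] + log(2)
  th2[model$idx$n] <- th[model$idx$n] + log(2)
  expect_equal(model2$nll(th2), v1, tolerance = 1e-8)
})

test_that("noise-free self-generated data is refit exactly", {
  dat <- small_fit_data(seed = 1)
  cfg <- reduced_configs()[[2]]
  model <- scaaens:::.make_scaa_model(dat, cfg)
  th_star <- scaaens:::.init_theta(dat, model, cfg)
  dec <- model$decode(th_star)
  chat <- baranov_catch(dec$state)
  surv <- lapply(seq_along(dat$surveys), function(s) {
    sv <- dat$surveys[[s]]
    list(index = (dec$q[[s]] * dec$state$n *
                    exp(-sv$timing * dec$state$z))[, sv$year_idx],
         timing = sv$timing, year_idx = sv$year_idx)
  })
  dat2 <- scaa_data(chat, dat$weight, dat$m, dat$maturity, surv)
  model2 <- scaaens:::.make_scaa_model(dat2, cfg)
  # generating parameters are a stationary point of the likelihood: with
  # zero residuals the residual sum of squares of every data source is
  # at its exact minimum, so the fixed-variance log-likelihood gradient
  # vanishes (the concentrated profile has a log cusp at a perfect fit,
  # so stationarity is asserted on the residual surface); central
  # differences, scaled against a nearby non-optimal point
  f0 <- model2$nll(th_star)
  rss <- function(th) {
    d <- model2$decode(th)
    ch <- baranov_catch(d$state)
    out <- sum((log(dat2$catch_n) - log(ch))^2)
    for (s in seq_along(dat2$surveys)) {
      sv <- dat2$surveys[[s]]
      ih <- (d$q[[s]] * d$state$n * exp(-sv$timing * d$state$z))[, sv$year_idx]
      out <- out + sum((log(sv$index) - log(ih))^2)
    }
    out
  }
  cgrad <- function(th) {
    vapply(seq_along(th), function(i) {
      e1 <- e2 <- th
      e1[i] <- e1[i] + 1e-6; e2[i] <- e2[i] - 1e-6
      (rss(e1) - rss(e2)) / 2e-6
    }, numeric(1))
  }
  g0 <- sqrt(sum(cgrad(th_star)^2))
  set.seed(2)
  g1 <- sqrt(sum(cgrad(th_star + rnorm(length(th_star), 0, 0.05))^2))
  expect_lt(g0 / g1, 1e-4)
  # nll at theta* not beaten by local perturbations
  set.seed(4)
  for (r in 1:10) {
    pert <- th_star + rnorm(length(th_star), 0, 0.02)
    expect_gte(model2$nll(pert), f0 - 1e-6)
  }
  # refit reproduces the generating catches
  fit <- fit_scaa(dat2, cfg)
  expect_lt(max(abs(baranov_catch(fit$state) - chat) / chat), 1e-6)
})

test_that("fitting is deterministic and the fit object is coherent", {
  dat <- small_fit_data(seed = 3)
  cfg <- reduced_configs()[[1]]
  f1 <- fit_scaa(dat, cfg)
  f2 <- fit_scaa(dat, cfg)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_true(f1$converged)
  expect_true(isSymmetric(f1$covariance, tol = 1e-8))
  expect_gt(min(eigen(f1$covariance, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_equal(compute_gcv(f1), f1$gcv)
  expect_gt(f1$gcv, 0)
})

test_that("GCV follows n RSS / (n - p)^2 and penalises overfitting", {
  fake <- structure(list(converged = TRUE, rss_catch = 2, n_catch = 4L,
                         p_catch = 2L), class = "scaa_fit")
  expect_equal(compute_gcv(fake), 4 * 2 / (4 - 2)^2)
  fake$p_catch <- 0L
  expect_equal(compute_gcv(fake), 2 / 4)
  fake$p_catch <- 4L
  expect_error(compute_gcv(fake), "fewer")
  # monotone in RSS
  g <- vapply(c(1, 2, 5), function(r) {
    fake$rss_catch <- r; fake$p_catch <- 2L; compute_gcv(fake)
  }, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("estimation-uncertainty resampling is centred with the fit
           covariance", {
  dat <- small_fit_data(seed = 5)
  fit <- fit_scaa(dat, reduced_configs()[[1]])
  expect_true(fit$converged)
  r1 <- sample_estimation_uncertainty(fit, 5, seed = 42)
  r2 <- sample_estimation_uncertainty(fit, 5, seed = 42)
  expect_identical(r1$draws, r2$draws)
  expect_equal(length(r1$summaries), 5L)
  big <- sample_estimation_uncertainty(fit, 10000, seed = 1)
  mu_err <- abs(colMeans(big$draws) - fit$theta_hat)
  sds <- sqrt(diag(fit$covariance))
  expect_lt(max(mu_err / (sds + 1e-12)), 0.1)   # ~1/sqrt(n) scaling
  emp <- stats::cov(big$draws)
  expect_lt(max(abs(emp - fit$covariance)) / max(abs(fit$covariance)),
            0.05)
  # zero covariance collapses all draws onto the estimate
  fit0 <- fit
  fit0$covariance <- matrix(0, length(fit$theta_hat),
                            length(fit$theta_hat))
  d0 <- sample_estimation_uncertainty(fit0, 3, seed = 1)
  expect_equal(d0$draws[1, ], fit$theta_hat, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- structure(list(converged = FALSE), class = "scaa_fit")
  expect_error(sample_estimation_uncertainty(bad, 1, 1), "non-converged")
})

test_that("grid has 18 configurations in the documented order", {
  grid <- scaa_grid(3)
  expect_length(grid, 18L)
  expect_equal(vapply(grid, `[[`, 0L, "id"), 1:18)
  expect_equal(grid[[1]]$fmodel$form, "age_year_factors")
  expect_equal(grid[[2]]$fmodel$form, "tensor_spline")
  expect_equal(grid[[3]]$fmodel$form, "logistic_age_by_year_smoother")
  expect_equal(grid[[4]]$qmodels[[1]]$form, "age_and_year_smoothers")
  expect_equal(grid[[10]]$rmodel$form, "ricker")
  expect_true(all(vapply(grid, function(g) length(g$qmodels), 0L) == 3L))
  forms <- vapply(grid, function(g)
    paste(g$fmodel$form, g$qmodels[[1]]$form, g$rmodel$form), "")
  expect_equal(anyDuplicated(forms), 0L)
})
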