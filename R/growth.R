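#' Triangle marginal distribution
#'
#' A triangle distribution on `[lower, upper]` with a single mode: the
#' density rises linearly from `lower` to `mode` and falls linearly to
#' `upper`.  Triangle marginals make very few assumptions about a
#' parameter beyond hard bounds and a central value, which makes them a
#' convenient way to express process uncertainty in life-history
#' parameters.  The central parameter is treated as the mode; for a
#' symmetric triangle (the default configuration for all three growth
#' parameters) mode and median coincide.
#'
#' @param lower,mode,upper numeric scalars, `lower <= mode <= upper`.
#' @return An object of class `triangle_marginal`.
#' @examples
#' tri <- triangle_marginal(104.52, 130, 155.48)
#' triangle_quantile(0.5, tri)
#' @export
triangle_marginal <- function(lower, mode, upper) {
  stopifnot(is.numeric(lower), is.numeric(mode), is.numeric(upper),
            length(lower) == 1L, length(mode) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(mode), is.finite(upper))
  if (lower > mode || mode > upper)
    stop("triangle_marginal requires lower <= mode <= upper")
  structure(list(lower = lower, mode = mode, upper = upper),
            class = "triangle_marginal")
}

#' @export
print.triangle_marginal <- function(x, ...) {
  cat(sprintf("triangle marginal: [%g, %g, %g] (lower, mode, upper)\n",
              x$lower, x$mode, x$upper))
  invisible(x)
}

#' Triangle bounds from a coefficient of variation
#'
#' Converts a central value and a coefficient of variation into symmetric
#' triangle bounds placed `z` standard deviations either side of the
#' centre, `lower = mode (1 - z cv)`, `upper = mode (1 + z cv)`.  With
#' `z = 1.96` the bounds cover approximately 95% of a normal spread of
#' the same cv.
#'
#' @param mode central value (parameter units).
#' @param cv coefficient of variation (dimensionless, `>= 0`).
#' @param z number of standard deviations to the bounds (default 1.96).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' triangle_bounds_from_cv(130, 0.10)    # c(104.52, 155.48)
#' @export
triangle_bounds_from_cv <- function(mode, cv, z = 1.96) {
  stopifnot(is.finite(mode), length(mode) == 1L,
            is.finite(cv), length(cv) == 1L,
            is.finite(z), length(z) == 1L, z > 0)
  if (cv < 0) stop("cv must be non-negative")
  c(lower = mode * (1 - z * cv), upper = mode * (1 + z * cv))
}

#' Triangle CDF
#'
#' @param x numeric vector of evaluation points.
#' @param marginal a [triangle_marginal()].
#' @return Vector of probabilities.
#' @export
triangle_cdf <- function(x, marginal) {
  stopifnot(inherits(marginal, "triangle_marginal"))
  a <- marginal$lower; m <- marginal$mode; b <- marginal$upper
  p <- numeric(length(x))
  if (b == a) return(as.numeric(x >= a))
  rising <- x > a & x <= m
  falling <- x > m & x < b
  if (m > a) p[rising] <- (x[rising] - a)^2 / ((b - a) * (m - a))
  # degenerate rising limb (a == m): mass starts falling immediately
  p[falling] <- 1 - (b - x[falling])^2 / ((b - a) * (b - m))
  if (m == a) p[x == m] <- 0
  p[x >= b] <- 1
  p
}

#' Triangle quantile function
#'
#' Inverse of the piecewise-quadratic triangle CDF; used to transform
#' copula uniforms onto the parameter scale.
#'
#' @param u probabilities in `[0, 1]`.
#' @param marginal a [triangle_marginal()].
#' @return Values on the marginal's support, monotone in `u`.
#' @export
triangle_quantile <- function(u, marginal) {
  stopifnot(inherits(marginal, "triangle_marginal"))
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must lie in [0, 1]")
  a <- marginal$lower; m <- marginal$mode; b <- marginal$upper
  if (b == a) return(rep(a, length(u)))
  fm <- (m - a) / (b - a)  # CDF value at the mode
  x <- numeric(length(u))
  lo <- u <= fm
  x[lo] <- a + sqrt(u[lo] * (b - a) * (m - a))
  x[!lo] <- b - sqrt((1 - u[!lo]) * (b - a) * (b - m))
  x
}

#' t-copula specification
#'
#' Dependence structure of a multivariate Student-t distribution, used to
#' couple the triangle marginals of the three von Bertalanffy parameters.
#' Only the correlation structure of the input matters: an unscaled
#' covariance matrix may be supplied and is converted to a correlation
#' matrix, so rescaling the input by any positive factor leaves the
#' sampled distribution unchanged.
#'
#' @param correlation 3x3 (or d x d) symmetric positive-definite matrix;
#'   a covariance matrix is accepted and standardised.
#' @param tail_df positive degrees of freedom of the t-copula.
#' @return An object of class `copula_spec`.
#' @export
copula_spec <- function(correlation, tail_df = 4) {
  stopifnot(is.matrix(correlation), nrow(correlation) == ncol(correlation),
            is.numeric(tail_df), length(tail_df) == 1L, tail_df > 0)
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("correlation matrix must be symmetric")
  d <- sqrt(diag(correlation))
  if (any(d <= 0)) stop("correlation matrix must have positive diagonal")
  r <- correlation / tcrossprod(d)   # covariance -> correlation
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("correlation matrix must be positive definite")
  structure(list(correlation = r, tail_df = tail_df), class = "copula_spec")
}

#' Default growth-parameter correlation
#'
#' Correlation structure for (Linf, k, t0) reflecting the sign pattern
#' typical of von Bertalanffy fits across demersal stocks: Linf and k
#' strongly negatively correlated, k and t0 positively correlated, Linf
#' and t0 weakly negatively correlated.  Fully user-overridable.
#'
#' @return 3x3 correlation matrix.
#' @export
default_growth_correlation <- function() {
  r <- diag(3)
  dimnames(r) <- list(c("linf", "k", "t0"), c("linf", "k", "t0"))
  r["linf", "k"] <- r["k", "linf"] <- -0.7
  r["k", "t0"] <- r["t0", "k"] <- 0.5
  r["linf", "t0"] <- r["t0", "linf"] <- -0.2
  r
}

#' Default triangle marginals for the growth parameters
#'
#' Symmetric triangles for Linf (centre 130 cm) and k (centre 0.164 1/yr)
#' with bounds at 1.96 standard deviations under a 10% cv, and a
#' symmetric triangle for t0 on `[-0.184, 0]` yr (centre -0.092).
#'
#' @param linf_mode,k_mode central values for Linf (cm) and k (1/yr).
#' @param cv coefficient of variation for the Linf and k bounds.
#' @param z standard-normal multiplier for the bounds.
#' @param t0_min,t0_max hard bounds for t0 (yr); the centre is their midpoint.
#' @return Named list of three [triangle_marginal()] objects.
#' @export
default_growth_marginals <- function(linf_mode = 130, k_mode = 0.164,
                                     cv = 0.10, z = 1.96,
                                     t0_min = -0.184, t0_max = 0) {
  bl <- triangle_bounds_from_cv(linf_mode, cv, z)
  bk <- triangle_bounds_from_cv(k_mode, cv, z)
  list(
    linf = triangle_marginal(bl[[1]], linf_mode, bl[[2]]),
    k    = triangle_marginal(bk[[1]], k_mode, bk[[2]]),
    t0   = triangle_marginal(t0_min, (t0_min + t0_max) / 2, t0_max)
  )
}

#' Growth parameter set
#'
#' One (Linf, k, t0) triple of von Bertalanffy parameters: `linf` the
#' asymptotic length (cm), `k` the growth rate (1/yr) and `t0` the
#' theoretical age at zero length (yr, `<= 0`).
#'
#' @param linf,k,t0 numeric scalars.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(linf, k, t0 = 0) {
  stopifnot(is.finite(linf), is.finite(k), is.finite(t0))
  if (linf <= 0) stop("linf must be positive")
  if (k <= 0) stop("k must be positive")
  if (t0 > 0) stop("t0 must be <= 0")
  structure(list(linf = linf, k = k, t0 = t0), class = "growth_params")
}

#' Sample correlated growth parameters from a t-copula
#'
#' Draws `n` (Linf, k, t0) sets by sampling a multivariate Student-t with
#' the copula's correlation and degrees of freedom, transforming each
#' coordinate to a uniform through the t CDF, and applying the inverse
#' triangle CDF of each marginal.  Draws are therefore guaranteed to lie
#' inside each marginal's hard bounds while preserving the requested rank
#' dependence.
#'
#' @param marginals named list with elements `linf`, `k`, `t0`, each a
#'   [triangle_marginal()].
#' @param copula a [copula_spec()].
#' @param n number of parameter sets to draw.
#' @param seed integer seed; identical seeds reproduce identical draws.
#' @return Object of class `growth_ensemble`: a list with `draws`
#'   (data.frame with columns linf, k, t0) and `seed`.
#' @examples
#' ge <- sample_growth_params(default_growth_marginals(),
#'                            copula_spec(default_growth_correlation()),
#'                            n = 10, seed = 1)
#' head(ge$draws)
#' @export
sample_growth_params <- function(marginals, copula, n, seed) {
  stopifnot(inherits(copula, "copula_spec"),
            all(c("linf", "k", "t0") %in% names(marginals)),
            n >= 1, length(n) == 1L)
  marginals <- marginals[c("linf", "k", "t0")]
  lapply(marginals, function(m) stopifnot(inherits(m, "triangle_marginal")))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  u <- .rtcopula(n, copula$correlation, copula$tail_df)
  draws <- data.frame(
    linf = triangle_quantile(u[, 1], marginals$linf),
    k    = triangle_quantile(u[, 2], marginals$k),
    t0   = triangle_quantile(u[, 3], marginals$t0)
  )
  structure(list(draws = draws, seed = as.integer(seed),
                 marginals = marginals, copula = copula),
            class = "growth_ensemble")
}

#' @export
print.growth_ensemble <- function(x, ...) {
  cat(sprintf("growth ensemble: %d draws (seed %d)\n",
              nrow(x$draws), x$seed))
  print(utils::head(x$draws, 3))
  if (nrow(x$draws) > 3) cat("...\n")
  invisible(x)
}

# Uniform samples with t-copula dependence: multivariate t via Cholesky of
# the correlation and a shared chi-square mixing variable, mapped through
# the univariate t CDF.
.rtcopula <- function(n, corr, df) {
  d <- ncol(corr)
  L <- chol(corr)
  z <- matrix(stats::rnorm(n * d), n, d) %*% L
  w <- sqrt(stats::rchisq(n, df) / df)
  stats::pt(z / w, df)
}

#' Extract one growth draw
#'
#' @param ensemble a `growth_ensemble`.
#' @param i iteration index.
#' @return A [growth_params()] object.
#' @export
growth_draw <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "growth_ensemble"))
  d <- ensemble$draws[i, ]
  growth_params(d$linf, d$k, min(d$t0, 0))
}

#' von Bertalanffy length at age
#'
#' `L(a) = linf (1 - exp(-k (a - t0)))`; strictly increasing in age and
#' asymptoting at `linf`.
#'
#' @param age ages (yr), each `>= t0`.
#' @param p a [growth_params()].
#' @return Lengths (cm).
#' @export
vb_length_at_age <- function(age, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(age < p$t0)) stop("age must be >= t0")
  p$linf * (1 - exp(-p$k * (age - p$t0)))
}

#' von Bertalanffy age at length (inverse growth curve)
#'
#' `a(L) = t0 - log(1 - L/linf) / k` for `0 <= L < linf`; used by the
#' length-slicing step to allocate length classes to ages.
#'
#' @param length lengths (cm) in `[0, linf)`.
#' @param p a [growth_params()].
#' @return Ages (yr).
#' @export
vb_age_at_length <- function(length, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(length < 0)) stop("length must be non-negative")
  if (any(length >= p$linf))
    stop("length must be below linf (asymptotic length)")
  p$t0 - log(1 - length / p$linf) / p$k
}

# RNG bookkeeping: stochastic operations take explicit seeds but must not
# disturb the caller's RNG stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
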