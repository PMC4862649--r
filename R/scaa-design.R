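#' Submodel specification for the catch-at-age model
#'
#' The statistical catch-at-age model is assembled from three pluggable
#' submodels: the fishing-mortality pattern (`fmodel`), the survey
#' catchability pattern (`qmodel`, one per index) and recruitment
#' (`rmodel`).  Admissible forms per role:
#'
#' * `fmodel`: `age_year_factors` (additive age and year factors on log F),
#'   `tensor_spline` (tensor product of cubic B-splines over age and year),
#'   `logistic_age_by_year_smoother` (logistic selectivity over age whose
#'   log plateau follows a year smoother).
#' * `qmodel`: `age_smoother` (B-spline over age, constant in time),
#'   `age_and_year_smoothers` (additive age and year B-splines),
#'   `logistic_age_by_year_smoother`.
#' * `rmodel`: `year_smoother` (B-spline over years on log recruitment),
#'   `ricker` (free annual recruitment shrunk towards a Ricker curve).
#'
#' @param role one of `"fmodel"`, `"qmodel"`, `"rmodel"`.
#' @param form submodel form (see above).
#' @param df optional named list with elements `age` and/or `year` giving
#'   basis dimensions; defaults follow [default_smoother_df()].
#' @return Object of class `submodel_spec`.
#' @export
submodel_spec <- function(role, form, df = NULL) {
  role <- match.arg(role, c("fmodel", "qmodel", "rmodel"))
  admissible <- list(
    fmodel = c("age_year_factors", "tensor_spline",
               "logistic_age_by_year_smoother"),
    qmodel = c("age_smoother", "age_and_year_smoothers",
               "logistic_age_by_year_smoother"),
    rmodel = c("year_smoother", "ricker"))
  form <- match.arg(form, admissible[[role]])
  structure(list(role = role, form = form, df = df),
            class = "submodel_spec")
}

#' @export
print.submodel_spec <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$role, x$form))
  invisible(x)
}

#' Default smoother basis dimensions
#'
#' Basis dimensions are adjusted to the data's size: the age margin uses
#' `min(6, n_ages - 2)` and the year margin `min(8, ceiling(n_years/4) + 2)`
#' degrees of freedom, floored at 2.
#'
#' @param n_ages,n_years numbers of modelled ages and years.
#' @return Named list with `age` and `year` df.
#' @export
default_smoother_df <- function(n_ages, n_years) {
  list(age = max(2L, min(6L, n_ages - 2L)),
       year = max(2L, min(8L, ceiling(n_years / 4) + 2L)))
}

# Cubic (or lower-order, for tiny df) B-spline basis including the
# intercept, so the columns form a partition of unity and a constant
# predictor corresponds to equal coefficients.
.bspline_basis <- function(x, df) {
  df <- as.integer(df)
  if (df > length(unique(x)))
    stop("smoother df exceeds the number of distinct levels")
  if (df == 1L) return(matrix(1, length(x), 1))
  degree <- min(3L, df - 1L)
  splines::bs(x, df = df, degree = degree, intercept = TRUE)
}

# Row-wise Kronecker product (tensor-product basis).
.row_kronecker <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), ncol(a) * ncol(b))
  for (j in seq_len(ncol(a)))
    out[, (j - 1L) * ncol(b) + seq_len(ncol(b))] <- a[, j] * b
  out
}

#' Build a submodel design
#'
#' Translates a [submodel_spec()] into a predictor over the age x year
#' grid.  Linear forms yield a design matrix whose rows follow the grid
#' in column-major order (age varying fastest); the logistic form is
#' nonlinear in (a50, log width) and is represented by a prediction
#' closure.  `rmodel` designs predict a per-year log-recruitment series.
#'
#' @param spec a [submodel_spec()].
#' @param ages,years modelled ages and years.
#' @return Object of class `scaa_design` with elements `form`, `npar`,
#'   and `predict(theta)` returning the log-scale predictor (an
#'   age x year matrix, or a year vector for rmodels).
#' @export
build_design <- function(spec, ages, years) {
  stopifnot(inherits(spec, "submodel_spec"))
  if (spec$role != "rmodel" && (length(ages) < 2 || length(years) < 2))
    stop("need at least 2 ages and 2 years")
  n_a <- length(ages); n_y <- length(years)
  dfd <- default_smoother_df(n_a, n_y)
  df_age <- spec$df$age %||% dfd$age
  df_year <- spec$df$year %||% dfd$year
  form <- spec$form

  if (form == "age_year_factors") {
    g <- expand.grid(age = factor(ages), year = factor(years))
    X <- stats::model.matrix(~ age + year, g)
    return(.linear_design(form, X, n_a, n_y))
  }
  if (form == "tensor_spline") {
    Ba <- .bspline_basis(ages, df_age)
    By <- .bspline_basis(years, df_year)
    X <- .row_kronecker(By[rep(seq_len(n_y), each = n_a), , drop = FALSE],
                        Ba[rep(seq_len(n_a), n_y), , drop = FALSE])
    return(.linear_design(form, X, n_a, n_y))
  }
  if (form == "age_smoother") {
    Ba <- .bspline_basis(ages, df_age)
    X <- Ba[rep(seq_len(n_a), n_y), , drop = FALSE]
    return(.linear_design(form, X, n_a, n_y))
  }
  if (form == "age_and_year_smoothers") {
    Ba <- .bspline_basis(ages, df_age)
    By <- .bspline_basis(years, df_year)
    # drop the year basis' first column: both bases sum to one, so the
    # full pair would be column-rank deficient
    X <- cbind(Ba[rep(seq_len(n_a), n_y), , drop = FALSE],
               By[rep(seq_len(n_y), each = n_a), -1, drop = FALSE])
    design <- .linear_design(form, X, n_a, n_y)
    design$n_age_cols <- ncol(Ba)
    return(design)
  }
  if (form == "year_smoother") {
    By <- .bspline_basis(years, df_year)
    if (spec$role == "rmodel") {
      design <- list(form = form, role = spec$role, npar = ncol(By),
                     basis = unclass(By),
                     predict = function(theta) drop(By %*% theta))
      class(design) <- "scaa_design"
      return(design)
    }
    X <- By[rep(seq_len(n_y), each = n_a), , drop = FALSE]
    return(.linear_design(form, X, n_a, n_y))
  }
  if (form == "ricker") {
    # free annual log recruitment; the Ricker parameters (log alpha,
    # log beta) enter only through the likelihood penalty
    npar <- n_y + 2L
    design <- list(form = form, role = spec$role, npar = npar,
                   n_years = n_y,
                   predict = function(theta) theta[seq_len(n_y)])
    class(design) <- "scaa_design"
    return(design)
  }
  if (form == "logistic_age_by_year_smoother") {
    By <- .bspline_basis(years, df_year)
    npar <- 2L + ncol(By)
    amat <- matrix(ages, n_a, n_y)
    design <- list(form = form, role = spec$role, npar = npar,
                   predict = function(theta) {
                     a50 <- theta[1]
                     delta <- exp(theta[2])
                     log_level <- drop(By %*% theta[-(1:2)])
                     sel <- stats::plogis((amat - a50) / delta)
                     sweep(log(pmax(sel, 1e-12)), 2, log_level, `+`)
                   })
    class(design) <- "scaa_design"
    return(design)
  }
  stop("unhandled form: ", form)
}

.linear_design <- function(form, X, n_a, n_y) {
  X <- unclass(X)
  design <- list(form = form, npar = ncol(X), X = X,
                 predict = function(theta)
                   matrix(X %*% theta, n_a, n_y))
  class(design) <- "scaa_design"
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stock assessment model configuration
#'
#' One combination of fmodel, qmodels and rmodel, plus the mean-F age
#' range and survey timings.
#'
#' @param fmodel a `submodel_spec` with role `fmodel`.
#' @param qmodels a single qmodel `submodel_spec` (applied to every
#'   survey) or a list with one spec per survey.
#' @param rmodel a `submodel_spec` with role `rmodel`.
#' @param fbar_range ages over which mean fishing mortality is taken.
#' @param survey_timing fractions of the year elapsed at each survey.
#' @param id optional integer label.
#' @return Object of class `scaa_config`.
#' @export
scaa_config <- function(fmodel, qmodels, rmodel, fbar_range = c(1, 3),
                        survey_timing = numeric(), id = NA_integer_) {
  stopifnot(inherits(fmodel, "submodel_spec"), fmodel$role == "fmodel",
            inherits(rmodel, "submodel_spec"), rmodel$role == "rmodel")
  if (inherits(qmodels, "submodel_spec")) qmodels <- list(qmodels)
  lapply(qmodels, function(q)
    stopifnot(inherits(q, "submodel_spec"), q$role == "qmodel"))
  stopifnot(length(fbar_range) == 2L, fbar_range[1] <= fbar_range[2])
  structure(list(fmodel = fmodel, qmodels = qmodels, rmodel = rmodel,
                 fbar_range = fbar_range, survey_timing = survey_timing,
                 id = id),
            class = "scaa_config")
}

#' @export
print.scaa_config <- function(x, ...) {
  cat(sprintf("SCAA config %s: f = %s, q = %s, r = %s\n",
              ifelse(is.na(x$id), "", x$id), x$fmodel$form,
              paste(unique(vapply(x$qmodels, `[[`, "", "form")),
                    collapse = "/"),
              x$rmodel$form))
  invisible(x)
}

#' The full submodel grid
#'
#' Crosses the three fmodels, three qmodels and two rmodels into the
#' 18 assessment-model configurations, ordered with the fmodel varying
#' fastest, then the qmodel, then the rmodel.  The same qmodel is applied
#' to every survey.
#'
#' @param n_surveys number of survey indices (the qmodel is replicated).
#' @param fbar_range,survey_timing passed to [scaa_config()].
#' @return List of 18 `scaa_config` objects with ids 1..18.
#' @export
scaa_grid <- function(n_surveys = 3,
                      fbar_range = c(1, 3),
                      survey_timing = rep(0.75, n_surveys)) {
  fforms <- c("age_year_factors", "tensor_spline",
              "logistic_age_by_year_smoother")
  qforms <- c("age_smoother", "age_and_year_smoothers",
              "logistic_age_by_year_smoother")
  rforms <- c("year_smoother", "ricker")
  configs <- list()
  id <- 0L
  for (rf in rforms) for (qf in qforms) for (ff in fforms) {
    id <- id + 1L
    configs[[id]] <- scaa_config(
      fmodel = submodel_spec("fmodel", ff),
      qmodels = replicate(n_surveys, submodel_spec("qmodel", qf),
                          simplify = FALSE),
      rmodel = submodel_spec("rmodel", rf),
      fbar_range = fbar_range, survey_timing = survey_timing, id = id)
  }
  configs
}
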