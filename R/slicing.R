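#' Length-frequency table
#'
#' Annual abundance by contiguous length classes of uniform width (1 cm
#' for catch data, 2 cm for survey indices, by convention).
#'
#' @param lower lower bounds of the length classes (cm), contiguous and
#'   uniformly spaced.
#' @param width class width (cm).
#' @param years years covered (ordered).
#' @param abundance matrix of non-negative abundances, one row per length
#'   class and one column per year.
#' @param unit free-text unit carried as metadata (e.g. `"thousands"`).
#' @return Object of class `length_frequency`.
#' @export
length_frequency <- function(lower, width, years, abundance,
                             unit = "count") {
  abundance <- as.matrix(abundance)
  stopifnot(length(lower) == nrow(abundance),
            length(years) == ncol(abundance))
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (length(lower) > 1) {
    d <- diff(lower)
    if (max(abs(d - width)) > 1e-9)
      stop("length classes must be contiguous with uniform width")
  }
  structure(list(lower = lower, width = width, years = years,
                 abundance = abundance, unit = unit),
            class = "length_frequency")
}

#' @export
print.length_frequency <- function(x, ...) {
  cat(sprintf(
    "length frequency: %d classes of %g cm (%g-%g cm), years %s-%s\n",
    length(x$lower), x$width, min(x$lower), max(x$lower) + x$width,
    min(x$years), max(x$years)))
  invisible(x)
}

#' Class midpoints of a length-frequency table
#' @param lf a `length_frequency`.
#' @return Numeric vector of midpoints (cm).
#' @export
midpoints <- function(lf) lf$lower + lf$width / 2

#' Weight-length relationship
#'
#' Allometric mean weight `W = a L^b`.
#'
#' @param a coefficient (weight units per cm^b), positive.
#' @param b exponent (dimensionless), positive.
#' @return Object of class `weight_length_params`.
#' @export
weight_length_params <- function(a = 6.59e-5, b = 3.01721) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "weight_length_params")
}

#' Mean weight at length
#' @param length lengths (cm).
#' @param wl a [weight_length_params()].
#' @return Weights in the coefficient's units.
#' @export
weight_at_length <- function(length, wl) {
  stopifnot(inherits(wl, "weight_length_params"))
  wl$a * length^wl$b
}

#' Allocate length classes to ages
#'
#' Deterministic slicing rule: each class is assigned
#' `floor(vb_age_at_length(midpoint))`, clamped below at age 0.  Classes
#' with midpoints at or above the draw's asymptotic length (where the
#' inverse growth curve is undefined) are assigned one more than the
#' oldest finite age on the grid, and are absorbed by the plusgroup
#' downstream.
#'
#' @param mids length-class midpoints (cm).
#' @param p a [growth_params()].
#' @return Integer age labels, non-decreasing in length.
#' @export
assign_ages <- function(mids, p) {
  stopifnot(inherits(p, "growth_params"))
  finite <- mids < p$linf
  age <- integer(length(mids))
  age[finite] <- pmax(0L, as.integer(floor(vb_age_at_length(mids[finite], p))))
  if (any(!finite)) {
    top <- if (any(finite)) max(age[finite]) else 0L
    age[!finite] <- top + 1L
  }
  age
}

#' Plusgroup age from a catch-biomass profile
#'
#' The plusgroup is the smallest age whose cumulative share of
#' time-averaged catch biomass reaches `threshold`.
#'
#' @param biomass_by_age named numeric vector of per-age biomass (names
#'   are ages), non-negative and not all zero.
#' @param threshold proportion in `(0, 1]` (default 0.95).
#' @return Integer age.
#' @export
compute_plusgroup <- function(biomass_by_age, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (any(biomass_by_age < 0) || all(biomass_by_age == 0))
    stop("biomass must be non-negative and not all zero")
  ages <- as.integer(names(biomass_by_age))
  if (anyNA(ages)) ages <- seq_along(biomass_by_age) - 1L
  o <- order(ages)
  share <- cumsum(biomass_by_age[o]) / sum(biomass_by_age)
  ages[o][which(share >= threshold - 1e-12)[1]]
}

# Aggregate one year's length-based vectors into ages 0..top.
# abundance: sums; weight: abundance-weighted mean (unweighted fallback
# when an age has zero abundance); m, maturity: unweighted means over the
# contributing classes.
.slice_year <- function(age_of_class, top, abund, wt_len, m_len, mat_len) {
  n_age <- top + 1L
  f <- factor(pmin(age_of_class, top), levels = 0:top)
  catch <- as.numeric(tapply(abund, f, sum, default = 0))
  num <- as.numeric(tapply(abund * wt_len, f, sum, default = 0))
  wt <- ifelse(catch > 0, num / catch, NA_real_)
  uw <- as.numeric(tapply(wt_len, f, mean, default = NA_real_))
  wt[is.na(wt)] <- uw[is.na(wt)]
  m <- as.numeric(tapply(m_len, f, mean, default = NA_real_))
  mat <- as.numeric(tapply(mat_len, f, mean, default = NA_real_))
  list(catch = catch, wt = wt, m = m, mat = mat)
}

# Fill ages with no contributing length classes by carrying the nearest
# populated age's biological values (abundance stays zero).
.fill_gaps <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (!length(idx)) stop("no populated age classes")
  near <- vapply(seq_along(v), function(i) idx[which.min(abs(idx - i))], 1L)
  v[near]
}

#' Slice a length-based stock into age-based data
#'
#' Converts length-based catch numbers, mean weight at length, natural
#' mortality and maturity into age-based matrices, once per growth draw.
#' Observations are allocated to ages with [assign_ages()] and aggregated:
#' sums for abundance, abundance-weighted means for mean weight,
#' unweighted means for natural mortality and maturity.  Each iteration
#' then receives its own plusgroup at the age containing `plusgroup_threshold`
#' of the time-averaged catch biomass; older ages are absorbed into it
#' with abundance weighting (which preserves total biomass).
#'
#' @param lf catch-at-length [length_frequency()].
#' @param wl a [weight_length_params()].
#' @param m_curve a [mortality_curve()] on the same length grid (single
#'   iteration, or one per growth draw).
#' @param maturity_at_length proportions mature per length class, in `[0,1]`.
#' @param growth a `growth_ensemble`.
#' @param plusgroup_threshold proportion of time-averaged catch biomass
#'   the plusgroup must contain (default 0.95).
#' @return Object of class `age_stock`: per-iteration lists of age x year
#'   matrices `catch_n`, `weight`, `m`, `maturity` (rows are ages
#'   `0:plusgroup`), a per-iteration `plusgroup`, plus `years`.
#' @export
slice_stock <- function(lf, wl, m_curve, maturity_at_length, growth,
                        plusgroup_threshold = 0.95) {
  stopifnot(inherits(lf, "length_frequency"),
            inherits(wl, "weight_length_params"),
            inherits(m_curve, "mortality_curve"),
            inherits(growth, "growth_ensemble"))
  mids <- midpoints(lf)
  if (length(m_curve$lengths) != length(mids) ||
      max(abs(m_curve$lengths - mids)) > 1e-6)
    stop("mortality curve must share the stock's length grid")
  if (length(maturity_at_length) != length(mids))
    stop("maturity ogive must share the stock's length grid")
  if (any(maturity_at_length < 0 | maturity_at_length > 1))
    stop("maturity must lie in [0, 1]")
  n_iter <- nrow(growth$draws)
  wt_len <- weight_at_length(mids, wl)
  n_year <- length(lf$years)

  iterations <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    p <- growth_draw(growth, i)
    age_cls <- assign_ages(mids, p)
    top <- max(age_cls)
    m_len <- m_curve$m[, min(i, ncol(m_curve$m))]
    sliced <- lapply(seq_len(n_year), function(y)
      .slice_year(age_cls, top, lf$abundance[, y], wt_len, m_len,
                  maturity_at_length))
    catch_n <- vapply(sliced, `[[`, numeric(top + 1L), "catch")
    weight <- vapply(sliced, `[[`, numeric(top + 1L), "wt")
    m <- vapply(sliced, `[[`, numeric(top + 1L), "m")
    maturity <- vapply(sliced, `[[`, numeric(top + 1L), "mat")
    catch_n <- matrix(catch_n, top + 1L, n_year)
    weight <- apply(matrix(weight, top + 1L, n_year), 2, .fill_gaps)
    m <- apply(matrix(m, top + 1L, n_year), 2, .fill_gaps)
    maturity <- apply(matrix(maturity, top + 1L, n_year), 2, .fill_gaps)
    weight <- matrix(weight, top + 1L, n_year)
    m <- matrix(m, top + 1L, n_year)
    maturity <- matrix(maturity, top + 1L, n_year)

    pg <- compute_plusgroup(
      stats::setNames(rowMeans(catch_n * weight), 0:top),
      plusgroup_threshold)
    it <- .apply_plusgroup(catch_n, weight, m, maturity, ages = 0:top,
                           plusgroup = pg)
    it$plusgroup <- pg
    dimnames(it$catch_n) <- dimnames(it$weight) <- dimnames(it$m) <-
      dimnames(it$maturity) <- list(age = 0:pg, year = lf$years)
    iterations[[i]] <- it
  }
  structure(list(iterations = iterations, years = lf$years,
                 n_iter = n_iter, unit = lf$unit,
                 mortality_model = m_curve$model_id),
            class = "age_stock")
}

# Collapse ages above the plusgroup into it: abundance summed; weight, m
# and maturity abundance-weighted (preserving biomass), with an unweighted
# fallback for all-zero years.
.apply_plusgroup <- function(catch_n, weight, m, maturity, ages, plusgroup) {
  keep <- ages <= plusgroup
  if (all(keep))
    return(list(catch_n = catch_n, weight = weight, m = m,
                maturity = maturity))
  idx <- which(ages >= plusgroup)
  wsum <- colSums(catch_n[idx, , drop = FALSE])
  agg <- function(x) {
    num <- colSums(catch_n[idx, , drop = FALSE] * x[idx, , drop = FALSE])
    ifelse(wsum > 0, num / wsum, colMeans(x[idx, , drop = FALSE]))
  }
  pg_row <- which(ages == plusgroup)
  weight[pg_row, ] <- agg(weight)
  m[pg_row, ] <- agg(m)
  maturity[pg_row, ] <- agg(maturity)
  catch_n[pg_row, ] <- wsum
  list(catch_n = catch_n[keep, , drop = FALSE],
       weight = weight[keep, , drop = FALSE],
       m = m[keep, , drop = FALSE],
       maturity = maturity[keep, , drop = FALSE])
}

#' @export
print.age_stock <- function(x, ...) {
  pg <- vapply(x$iterations, `[[`, 1L, "plusgroup")
  cat(sprintf(
    "age stock ('%s' M): %d iterations, years %s-%s, plusgroups %d-%d\n",
    x$mortality_model, x$n_iter, min(x$years), max(x$years),
    min(pg), max(pg)))
  invisible(x)
}

#' Slice a survey index into age-based data
#'
#' Sums index abundance into ages with the same growth draws as the
#' stock, so the age-class boundaries of stock and index agree iteration
#' by iteration; the stock's per-iteration plusgroup is applied.
#'
#' @param index a [length_frequency()] on the survey's own (2 cm) grid.
#' @param growth the shared `growth_ensemble`.
#' @param plusgroup per-iteration plusgroup ages (e.g. from the sliced
#'   stock), recycled if scalar.
#' @param timing fraction of the year elapsed when the survey runs, in
#'   `[0, 1)`.
#' @return Object of class `age_index`: per-iteration abundance matrices
#'   (rows ages `0:plusgroup`), `years`, `timing`.
#' @export
slice_index <- function(index, growth, plusgroup, timing = 0) {
  stopifnot(inherits(index, "length_frequency"),
            inherits(growth, "growth_ensemble"),
            timing >= 0, timing < 1)
  n_iter <- nrow(growth$draws)
  plusgroup <- rep_len(plusgroup, n_iter)
  mids <- midpoints(index)
  iterations <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    p <- growth_draw(growth, i)
    age_cls <- pmin(assign_ages(mids, p), plusgroup[i])
    f <- factor(age_cls, levels = 0:plusgroup[i])
    ab <- apply(index$abundance, 2, function(col)
      as.numeric(tapply(col, f, sum, default = 0)))
    ab <- matrix(ab, plusgroup[i] + 1L, length(index$years),
                 dimnames = list(age = 0:plusgroup[i], year = index$years))
    iterations[[i]] <- ab
  }
  structure(list(iterations = iterations, years = index$years,
                 timing = timing, n_iter = n_iter),
            class = "age_index")
}

#' @export
print.age_index <- function(x, ...) {
  cat(sprintf("age index: %d iterations, years %s-%s, timing %.3f\n",
              x$n_iter, min(x$years), max(x$years), x$timing))
  invisible(x)
}
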