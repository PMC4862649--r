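#' Project an age-structured population
#'
#' Standard exponential-survival accounting with a plusgroup:
#' `N(a+1, y+1) = N(a, y) exp(-Z(a, y))` for ages below the plusgroup,
#' and the plusgroup accumulates its own survivors,
#' `N(A, y+1) = N(A-1, y) e^{-Z(A-1, y)} + N(A, y) e^{-Z(A, y)}`.
#' The first row is recruitment, the remainder of the first column the
#' initial age structure.
#'
#' @param recruits recruitment per year (first age class), length Y.
#' @param n_init abundance of ages 2..A+1 in the first year, length A-1
#'   for an A-age model (i.e. all ages above the first).
#' @param f,m age x year matrices of fishing and natural mortality (1/yr).
#' @return Object of class `population_state`: list of matrices `n`, `f`,
#'   `m`, `z`.
#' @export
project_population <- function(recruits, n_init, f, m) {
  f <- as.matrix(f); m <- as.matrix(m)
  n_a <- nrow(f); n_y <- ncol(f)
  stopifnot(ncol(m) == n_y, nrow(m) == n_a,
            length(recruits) == n_y, length(n_init) == n_a - 1L)
  if (any(recruits < 0) || any(n_init < 0) || any(f < 0) || any(m < 0))
    stop("abundances and mortality rates must be non-negative")
  z <- f + m
  n <- matrix(NA_real_, n_a, n_y, dimnames = dimnames(f))
  n[1, ] <- recruits
  n[-1, 1] <- n_init
  if (n_y > 1) {
    s <- exp(-z)
    for (y in seq_len(n_y - 1L)) {
      if (n_a > 1) {
        n[-1, y + 1L] <- n[-n_a, y] * s[-n_a, y]
        n[n_a, y + 1L] <- n[n_a, y + 1L] + n[n_a, y] * s[n_a, y]
      } else {
        n[1, y + 1L] <- recruits[y + 1L] + n[1, y] * s[1, y]
      }
    }
  }
  structure(list(n = n, f = f, m = m, z = z), class = "population_state")
}

#' Baranov catch equation
#'
#' `C = (F/Z)(1 - e^{-Z}) N`: the catch taken from each age-year cell
#' under competing fishing and natural mortality.  Cells with `F = 0`
#' yield zero catch.
#'
#' @param state a [project_population()] result, or any list with
#'   matrices `n`, `f`, `z`.
#' @return Age x year matrix of predicted catch numbers.
#' @export
baranov_catch <- function(state) {
  f <- state$f; z <- state$z
  out <- matrix(0, nrow(f), ncol(f), dimnames = dimnames(f))
  pos <- f > 0
  out[pos] <- f[pos] / z[pos] * (1 - exp(-z[pos])) * state$n[pos]
  out
}

#' Predicted survey index
#'
#' `I(a, y) = q(a, y) N(a, y) e^{-timing Z(a, y)}`: survey catchability
#' applied to mid-survey abundance.
#'
#' @param state a `population_state`.
#' @param q age x year catchability matrix.
#' @param timing fraction of the year elapsed at the survey, in `[0, 1)`.
#' @return Age x year matrix of predicted index values.
#' @export
predict_index <- function(state, q, timing = 0) {
  stopifnot(timing >= 0, timing < 1)
  q * state$n * exp(-timing * state$z)
}

#' Summary series from a population state
#'
#' Computes the standard assessment summary per year: recruitment (first
#' age class), spawning stock biomass `SSB = sum_a N w mat`, mean fishing
#' mortality over `fbar_range`, catch biomass `sum_a C w`, and harvest
#' rate (catch biomass / total stock biomass).
#'
#' @param state a `population_state`.
#' @param weight,maturity age x year matrices of mean weight and maturity.
#' @param fbar_range age interval `c(lo, hi)` for mean F.
#' @param ages the ages corresponding to the state's rows (default
#'   `0:(A-1)`).
#' @return `data.frame` with columns `year` (index), `recruitment`,
#'   `ssb`, `fbar`, `catch`, `harvest_rate`.
#' @export
summarize_fit <- function(state, weight, maturity, fbar_range = c(1, 3),
                          ages = seq_len(nrow(state$n)) - 1L) {
  n <- state$n
  stopifnot(all(dim(weight) == dim(n)), all(dim(maturity) == dim(n)))
  fb <- ages >= fbar_range[1] & ages <= fbar_range[2]
  if (!any(fb)) fb <- rep(TRUE, length(ages))
  catch_n <- baranov_catch(state)
  biomass <- colSums(n * weight)
  catch_b <- colSums(catch_n * weight)
  data.frame(
    year = seq_len(ncol(n)),
    recruitment = n[1, ],
    ssb = colSums(n * weight * maturity),
    fbar = colMeans(state$f[fb, , drop = FALSE]),
    catch = catch_b,
    harvest_rate = ifelse(biomass > 0, catch_b / biomass, 0),
    row.names = NULL
  )
}
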