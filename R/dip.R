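#' Hartigan's dip statistic
#'
#' The maximum absolute distance between the empirical CDF of `x` and
#' the closest unimodal CDF (convex up to its mode, concave after it,
#' with an atom permitted at the mode).  Large values indicate
#' multimodality.  The statistic respects the classical lower bound
#' `1/(2n)`, which is also the value returned for degenerate (constant)
#' samples.
#'
#' @param x numeric sample, `length(x) >= 2`.
#' @return Scalar dip statistic in `[1/(2n), 1/4]`.
#' @examples
#' dip_statistic(c(0, 0, 1, 1))   # 0.25, the two-point-mass maximum
#' @export
dip_statistic <- function(x) {
  if (length(x) < 2) stop("dip statistic requires at least 2 observations")
  if (any(!is.finite(x))) stop("sample must be finite")
  dip_stat_cpp(as.numeric(x))
}

#' Null distribution of the dip statistic
#'
#' Dip statistics of `n_boot` uniform(0, 1) samples of size `n`
#' (Hartigan's calibration null).  The null depends only on `n`, so a
#' computed batch can be reused across tests of equally sized samples.
#'
#' @param n sample size.
#' @param n_boot number of bootstrap samples (`>= 100`).
#' @param seed integer seed.
#' @return Numeric vector of `n_boot` dip statistics.
#' @export
dip_null <- function(n, n_boot = 2000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(n * n_boot), nrow = n)
  dip_stat_columns(u)
}

#' Dip test for multimodality
#'
#' Bootstrap test of unimodality: the p-value is the proportion of
#' uniform(0, 1) samples of the same size whose dip statistic is at
#' least the observed one.
#'
#' @param x numeric sample, `length(x) >= 10`.
#' @param n_boot bootstrap replicates (`>= 100`).
#' @param seed integer seed for the bootstrap null.
#' @param alpha significance level for the rejection flag.
#' @param null_dips optional precomputed [dip_null()] batch for
#'   `length(x)` (skips the bootstrap).
#' @return Object of class `dip_test` (a list): `dip`, `p_value`,
#'   `rejected`, `n`, `n_boot`.
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1, alpha = 0.05,
                     null_dips = NULL) {
  if (length(x) < 10) stop("dip test requires at least 10 observations")
  dip <- dip_statistic(x)
  if (is.null(null_dips)) {
    null_dips <- dip_null(length(x), n_boot, seed)
  }
  p <- mean(null_dips >= dip)
  structure(list(dip = dip, p_value = p, rejected = p < alpha,
                 n = length(x), n_boot = length(null_dips), alpha = alpha),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.5f, p = %.4f (n = %d, %s)\n",
              x$dip, x$p_value, x$n,
              if (x$rejected) "multimodal" else "unimodal not rejected"))
  invisible(x)
}

# ---------------------------------------------------------------------
# Brute-force reference implementation.
#
# Direct numerical minimisation over unimodal CDFs: for every candidate
# mode (each data point, and a continuous search inside every gap) the
# smallest uniform band half-width is found from greatest-convex-
# minorant / least-concave-majorant constructions evaluated through an
# O(k^3) min-over-chords rule, including an explicit check that the
# convex and concave branches can be joined monotonically at the mode
# (bisecting the band width when they cannot).  Exponentially slower
# than dip_statistic() but derived independently; intended for
# validation on small samples.
# ---------------------------------------------------------------------

# greatest convex minorant of points (px, py) evaluated at px
.gcm_eval <- function(px, py) {
  k <- length(px)
  if (k == 1) return(py)
  out <- py
  for (p in seq_len(k - 1)) for (q in (p + 1):k) {
    d <- p:q
    val <- py[p] + (py[q] - py[p]) * (px[d] - px[p]) / (px[q] - px[p])
    out[d] <- pmin(out[d], val)
  }
  out
}

.lcm_eval <- function(px, py) -.gcm_eval(px, -py)

# smallest value a convex nondecreasing branch within the band can take
# at its right end (the candidate mode): the largest of the lower
# constants and of upper-through-lower chords extended with slope
# floored at zero.  `px` ends at the mode.
.v_left_min <- function(px, lower0, upper0, rho) {
  k <- length(px)
  lows <- lower0 - rho
  best <- max(lows)
  if (k >= 2) {
    m <- px[k]
    for (q in 2:k) {
      p <- seq_len(q - 1)
      s <- (lows[q] - (upper0[p] + rho)) / (px[q] - px[p])
      best <- max(best, lows[q] + pmax(0, s) * (m - px[q]))
    }
  }
  best
}

# mirrored: largest value the concave branch can start from at its left
# end (`px` starts at the mode).
.v_right_max <- function(px, lower0, upper0, rho) {
  -.v_left_min(rev(-px), rev(-upper0), rev(-lower0), rho)
}

#' Brute-force dip statistic (validation reference)
#'
#' Independent, slow computation of the dip by direct minimisation over
#' unimodal CDFs; see [dip_statistic()] for the definition.  Use only on
#' small samples (roughly `n <= 12`).
#'
#' @param x numeric sample, `length(x) >= 2`.
#' @return Scalar dip statistic.
#' @export
dip_statistic_brute <- function(x) {
  n <- length(x)
  if (n < 2) stop("dip statistic requires at least 2 observations")
  xs <- sort(x)
  keep <- !duplicated(xs)
  v <- xs[keep]
  hi <- cumsum(tabulate(match(xs, v), length(v))) / n
  lo <- c(0, hi[-length(hi)])
  D <- length(v)
  floor_dip <- 0.5 / n
  if (D == 1) return(floor_dip)

  left_sides <- function(i, tx, ty) {     # data corners d <= i
    list(px = c(v[seq_len(i)], tx),
         upper0 = c(lo[seq_len(i)], ty),  # unshifted upper-band heights
         lower0 = c(hi[seq_len(i)], ty))
  }
  right_sides <- function(j, tx, ty) {    # data corners d >= j
    idx <- if (j <= D) j:D else integer()
    list(px = c(tx, v[idx]),
         lower0 = c(ty, hi[idx]),
         upper0 = c(ty, lo[idx]))
  }
  rho_sides <- function(L, R) {
    rl <- if (length(L$px) > 1)
      max(L$lower0 - .gcm_eval(L$px, L$upper0)) / 2 else 0
    rr <- if (length(R$px) > 1)
      max(.lcm_eval(R$px, R$lower0) - R$upper0) / 2 else 0
    max(rl, rr, 0)
  }
  junction_ok <- function(L, R, rho) {
    .v_left_min(L$px, L$lower0, L$upper0, rho) <=
      .v_right_max(R$px, R$lower0, R$upper0, rho) + 1e-13
  }
  rho_mode <- function(L, R) {
    rs <- rho_sides(L, R)
    if (junction_ok(L, R, rs)) return(rs)
    lohi <- c(rs, 0.6)
    for (it in 1:45) {
      mid <- mean(lohi)
      if (junction_ok(L, R, mid)) lohi[2] <- mid else lohi[1] <- mid
    }
    lohi[2]
  }

  best <- Inf
  for (j in seq_len(D)) {   # mode at a data point, atom absorbing its jump
    val <- rho_mode(left_sides(j - 1L, v[j], lo[j]),
                    right_sides(j + 1L, v[j], hi[j]))
    best <- min(best, val)
  }
  if (D > 1) {
    for (g in seq_len(D - 1L)) {  # mode inside the gap (v_g, v_{g+1})
      f <- function(m) rho_mode(left_sides(g, m, hi[g]),
                                right_sides(g + 1L, m, hi[g]))
      opt <- stats::optimize(f, interval = c(v[g], v[g + 1]), tol = 1e-10)
      best <- min(best, opt$objective,
                  f(v[g] + 1e-9 * (v[g + 1] - v[g])),
                  f(v[g + 1] - 1e-9 * (v[g + 1] - v[g])))
    }
  }
  max(best, floor_dip)
}
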