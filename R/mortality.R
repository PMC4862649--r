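#' Length-based natural mortality curve
#'
#' Container for natural mortality at length, possibly with several
#' iterations reflecting process uncertainty in the growth parameters.
#'
#' @param lengths length-class midpoints (cm), ordered.
#' @param m matrix of mortality rates (1/yr), one row per length class and
#'   one column per iteration (a vector is taken as a single iteration).
#' @param model_id `"constant"` or `"gislason"`.
#' @return Object of class `mortality_curve`.
#' @export
mortality_curve <- function(lengths, m, model_id) {
  model_id <- match.arg(model_id, c("constant", "gislason"))
  m <- as.matrix(m)
  if (length(lengths) != nrow(m))
    stop("m must have one row per length class")
  if (length(lengths) && any(m <= 0))
    stop("all mortality rates must be positive")
  structure(list(lengths = lengths, m = m, model_id = model_id),
            class = "mortality_curve")
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("mortality curve ('%s'): %d length classes, %d iteration(s)\n",
              x$model_id, length(x$lengths), ncol(x$m)))
  invisible(x)
}

#' Constant natural mortality
#'
#' The status-quo model: a single fixed rate at every length (and year),
#' with no process uncertainty.
#'
#' @param lengths length-class midpoints (cm).
#' @param value mortality rate (1/yr), positive; 0.4 is the conventional
#'   assessment value for hake-like demersal stocks.
#' @return A single-iteration `mortality_curve`.
#' @export
constant_m <- function(lengths, value = 0.4) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (value <= 0) stop("constant mortality must be positive")
  mortality_curve(lengths, matrix(value, length(lengths), 1),
                  model_id = "constant")
}

#' Gislason length-based natural mortality
#'
#' Gislason's second estimator, `m(len) = k (linf / len)^1.5`: natural
#' mortality falls steeply with length, so small (young) fish die at much
#' higher rates.
#'
#' @param length lengths (cm), positive.
#' @param p a [growth_params()].
#' @return Mortality rates (1/yr), strictly decreasing in length.
#' @export
gislason_m <- function(length, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(length <= 0)) stop("length must be positive")
  p$k * (p$linf / length)^1.5
}

#' Rescale a mortality curve to Jensen's level
#'
#' Multiplies each iteration of the curve by the scalar that makes the
#' arithmetic mean of m over the length classes inside `window` equal to
#' Jensen's second estimator `1.5 k` (the window covers the most exploited
#' lengths).  The shape of the curve is unchanged; applying the scaling
#' twice is a no-op.
#'
#' @param curve a `mortality_curve`.
#' @param k growth rate(s) (1/yr): a scalar or one value per iteration.
#' @param window closed length interval `c(lo, hi)` in cm; classes whose
#'   midpoints fall inside it enter the mean.
#' @return A rescaled `mortality_curve`.
#' @export
jensen_scale <- function(curve, k, window = c(15, 60)) {
  stopifnot(inherits(curve, "mortality_curve"), length(window) == 2L)
  inside <- curve$lengths >= window[1] & curve$lengths <= window[2]
  if (!any(inside)) stop("window does not intersect the curve's length grid")
  k <- rep_len(k, ncol(curve$m))
  mean_in <- colMeans(curve$m[inside, , drop = FALSE])
  scale <- 1.5 * k / mean_in
  mortality_curve(curve$lengths,
                  sweep(curve$m, 2, scale, `*`),
                  model_id = curve$model_id)
}

#' Build a natural mortality ensemble
#'
#' For the `"gislason"` model, evaluates the Gislason curve with each
#' growth draw's (linf, k) and rescales it to that draw's Jensen level
#' `1.5 k`, inheriting the growth ensemble's process uncertainty.  For
#' the `"constant"` model, returns one deterministic curve (zero
#' across-iteration variance).
#'
#' @param model_id `"constant"` or `"gislason"`.
#' @param lengths length-class midpoints (cm).
#' @param growth a `growth_ensemble` (required for `"gislason"`).
#' @param constant_value rate for the constant model (1/yr).
#' @param jensen_window length window (cm) for the Jensen rescaling.
#' @return A `mortality_curve` with one column per growth draw
#'   (`"gislason"`) or a single column (`"constant"`).
#' @export
build_mortality_ensemble <- function(model_id, lengths, growth = NULL,
                                     constant_value = 0.4,
                                     jensen_window = c(15, 60)) {
  model_id <- match.arg(model_id, c("constant", "gislason"))
  if (length(lengths) == 0) stop("lengths must be non-empty")
  if (model_id == "constant")
    return(constant_m(lengths, constant_value))
  stopifnot(inherits(growth, "growth_ensemble"))
  n <- nrow(growth$draws)
  if (n == 0) stop("growth ensemble must be non-empty for the gislason model")
  m <- vapply(seq_len(n), function(i) {
    gislason_m(lengths, growth_draw(growth, i))
  }, numeric(length(lengths)))
  jensen_scale(mortality_curve(lengths, m, "gislason"),
               k = growth$draws$k, window = jensen_window)
}
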