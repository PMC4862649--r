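#' Model variant
#'
#' One cell of the assessment grid: a stock-assessment configuration
#' crossed with a natural-mortality model, holding the summary series
#' and GCV scores of all iterations that fitted successfully.
#'
#' @param sa_config_id assessment configuration id (1..18 on the full
#'   grid).
#' @param mortality_model `"constant"` or `"gislason"`.
#' @param summaries list of per-iteration [summarize_fit()] data frames.
#' @param gcv numeric vector of per-iteration GCV scores (same length).
#' @param iteration_ids original iteration indices (defaults to
#'   `seq_along(summaries)`).
#' @return Object of class `model_variant`.
#' @export
model_variant <- function(sa_config_id, mortality_model, summaries, gcv,
                          iteration_ids = seq_along(summaries)) {
  mortality_model <- match.arg(mortality_model, c("constant", "gislason"))
  stopifnot(length(gcv) == length(summaries),
            length(iteration_ids) == length(summaries))
  structure(list(sa_config_id = sa_config_id,
                 mortality_model = mortality_model,
                 summaries = summaries, gcv = gcv,
                 iteration_ids = iteration_ids,
                 n_success = length(summaries)),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("model variant: SA %s x '%s' M, %d successful iterations\n",
              x$sa_config_id, x$mortality_model, x$n_success))
  invisible(x)
}

.final_harvest_rates <- function(variant) {
  vapply(variant$summaries, function(s) s$harvest_rate[nrow(s)], numeric(1))
}

#' Filter unstable model variants by the dip test
#'
#' A variant whose final-year harvest rates are multimodal reflects an
#' unstable mix of fits rather than a plausible state of nature; such
#' variants are rejected.  Variants with too few successful iterations
#' are also rejected.
#'
#' @param variants list of `model_variant` objects.
#' @param alpha significance level of the dip test.
#' @param n_boot bootstrap replicates for the dip null.
#' @param seed integer seed for the bootstrap null.
#' @param min_iterations minimum number of successful iterations a
#'   variant needs to be considered (default 10, the dip test's floor).
#' @return List with `retained` (surviving variants) and `report`
#'   (data.frame: sa_config_id, mortality_model, n_success, dip,
#'   p_value, rejected, reason).
#' @export
filter_variants <- function(variants, alpha = 0.05, n_boot = 2000,
                            seed = 1, min_iterations = 10) {
  if (!length(variants))
    return(list(retained = list(),
                report = data.frame(sa_config_id = integer(),
                                    mortality_model = character(),
                                    n_success = integer(), dip = numeric(),
                                    p_value = numeric(), rejected = logical(),
                                    reason = character())))
  nulls <- new.env()
  rows <- lapply(variants, function(v) {
    if (v$n_success < min_iterations) {
      return(data.frame(sa_config_id = v$sa_config_id,
                        mortality_model = v$mortality_model,
                        n_success = v$n_success, dip = NA_real_,
                        p_value = NA_real_, rejected = TRUE,
                        reason = "insufficient iterations"))
    }
    hr <- .final_harvest_rates(v)
    if (length(hr) < 10) {
      # below the dip test's sample-size floor: retained untested
      return(data.frame(sa_config_id = v$sa_config_id,
                        mortality_model = v$mortality_model,
                        n_success = v$n_success, dip = NA_real_,
                        p_value = NA_real_, rejected = FALSE,
                        reason = "too few iterations for dip test"))
    }
    key <- as.character(length(hr))
    if (is.null(nulls[[key]]))
      nulls[[key]] <- dip_null(length(hr), n_boot, seed)
    dt <- dip_test(hr, alpha = alpha, null_dips = nulls[[key]])
    data.frame(sa_config_id = v$sa_config_id,
               mortality_model = v$mortality_model,
               n_success = v$n_success, dip = dt$dip,
               p_value = dt$p_value, rejected = dt$rejected,
               reason = ifelse(dt$rejected, "bimodal harvest rates", ""))
  })
  report <- do.call(rbind, rows)
  list(retained = variants[!report$rejected], report = report)
}

#' Inverse-median-GCV variant weights
#'
#' Each variant is weighted by the inverse of the median GCV across its
#' iterations, normalised to sum to one: variants with better average
#' predictive power receive more weight.  Weights are invariant to
#' rescaling all GCVs by a common positive factor.
#'
#' @param variants list of `model_variant` objects with positive GCVs.
#' @return Numeric weight vector summing to 1.
#' @export
gcv_weights <- function(variants) {
  stopifnot(length(variants) >= 1)
  med <- vapply(variants, function(v) {
    if (!length(v$gcv)) stop("variant has no GCV values")
    if (any(!is.finite(v$gcv)) || any(v$gcv <= 0))
      stop("GCV scores must be positive and finite")
    stats::median(v$gcv)
  }, numeric(1))
  w <- 1 / med
  w / sum(w)
}

#' The single best variant by median GCV
#'
#' @param variants list of `model_variant` objects.
#' @return The variant with the lowest median GCV.
#' @export
best_variant <- function(variants) {
  med <- vapply(variants, function(v) stats::median(v$gcv), numeric(1))
  variants[[which.min(med)]]
}

#' Model-average iterations across variants
#'
#' Two-stage sampling: each of the `n_select` slots picks a variant with
#' probability proportional to its weight, then an as-yet-unused
#' iteration uniformly at random within that variant (without
#' replacement within a variant).  `n_select` may not exceed the
#' smallest variant's number of successful iterations, so no iteration
#' is ever reused.
#'
#' @param variants list of `model_variant` objects.
#' @param weights per-variant probabilities (e.g. [gcv_weights()]).
#' @param n_select number of iterations in the averaged result; defaults
#'   to the minimum `n_success` across variants.
#' @param seed integer seed.
#' @return Object of class `ensemble_result`: `summaries` (selected
#'   iteration series), `provenance` (data.frame variant / sa_config_id /
#'   mortality_model / iteration), `weights`.
#' @export
model_average <- function(variants, weights, n_select = NULL, seed = 1) {
  stopifnot(length(variants) >= 1, length(weights) == length(variants))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  n_min <- min(vapply(variants, `[[`, 0L, "n_success"))
  if (is.null(n_select)) n_select <- n_min
  if (n_select > n_min)
    stop("n_select cannot exceed the smallest variant's successful ",
         "iterations (", n_min, ")")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  pick_variant <- sample.int(length(variants), n_select, replace = TRUE,
                             prob = weights)
  pool <- lapply(variants, function(v) sample(seq_len(v$n_success)))
  used <- integer(length(variants))
  prov <- data.frame(variant = pick_variant, iteration = NA_integer_)
  summaries <- vector("list", n_select)
  for (k in seq_len(n_select)) {
    vi <- pick_variant[k]
    used[vi] <- used[vi] + 1L
    it <- pool[[vi]][used[vi]]
    prov$iteration[k] <- variants[[vi]]$iteration_ids[it]
    summaries[[k]] <- variants[[vi]]$summaries[[it]]
  }
  ids <- vapply(variants, function(v) as.integer(v$sa_config_id), integer(1))
  mm <- vapply(variants, `[[`, "", "mortality_model")
  prov$sa_config_id <- ids[prov$variant]
  prov$mortality_model <- mm[prov$variant]
  structure(list(summaries = summaries, provenance = prov,
                 weights = weights, seed = as.integer(seed)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble result: %d iterations drawn from %d variants\n",
              length(x$summaries), length(x$weights)))
  invisible(x)
}

#' Quantile summaries of an ensemble
#'
#' Empirical per-year quantiles of recruitment, SSB, mean F, catch and
#' harvest rate across the selected iterations.
#'
#' @param result an `ensemble_result` (or any list of [summarize_fit()]
#'   data frames in `$summaries`).
#' @param quantiles probabilities (default 10%, median, 90%).
#' @return Long data.frame with columns `year`, `quantity`, `quantile`,
#'   `value`.
#' @export
summarize_ensemble <- function(result,
                               quantiles = c(0.1, 0.5, 0.9)) {
  summaries <- result$summaries
  stopifnot(length(summaries) >= 1)
  quantities <- c("recruitment", "ssb", "fbar", "catch", "harvest_rate")
  years <- summaries[[1]]$year
  out <- list()
  for (q in quantities) {
    mat <- vapply(summaries, function(s) s[[q]], numeric(length(years)))
    mat <- matrix(mat, length(years))
    for (p in quantiles) {
      out[[length(out) + 1L]] <- data.frame(
        year = years, quantity = q, quantile = p,
        value = apply(mat, 1, stats::quantile, probs = p, names = FALSE))
    }
  }
  do.call(rbind, out)
}
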