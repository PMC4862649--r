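#' Read a length-frequency table
#'
#' Reads a header-bearing delimited table with columns `year`,
#' `length_lower`, `value` into a [length_frequency()].  The uniform
#' class width is inferred from the spacing of the length bounds;
#' missing (year, length) cells are treated as zero with a warning;
#' duplicated cells and non-numeric values are errors.
#'
#' @param path file path (CSV).
#' @param unit unit metadata to attach.
#' @return A [length_frequency()].
#' @export
read_length_table <- function(path, unit = "count") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "length_lower", "value")
  if (!all(need %in% names(df)))
    stop("length table must have columns year, length_lower, value")
  for (col in need) {
    vals <- df[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(vals))))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]))
    df[[col]] <- as.numeric(vals)
  }
  key <- paste(df$year, df$length_lower)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (year, length) pair at data row %d",
                 anyDuplicated(key)))
  lower <- sort(unique(df$length_lower))
  years <- sort(unique(df$year))
  if (length(lower) > 1) {
    w <- diff(lower)
    if (max(abs(w - w[1])) > 1e-9)
      stop("mixed length-class widths in table")
    width <- w[1]
  } else width <- 1
  ab <- matrix(0, length(lower), length(years))
  ab[cbind(match(df$length_lower, lower), match(df$year, years))] <- df$value
  if (nrow(df) < length(lower) * length(years))
    warning(sprintf("%d missing (year, length) cells treated as zero",
                    length(lower) * length(years) - nrow(df)))
  length_frequency(lower, width, years, ab, unit = unit)
}

#' Write a length-frequency table
#'
#' Long-format CSV counterpart of [read_length_table()].
#'
#' @param lf a [length_frequency()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_length_table <- function(lf, path) {
  stopifnot(inherits(lf, "length_frequency"))
  df <- data.frame(
    year = rep(lf$years, each = length(lf$lower)),
    length_lower = rep(lf$lower, length(lf$years)),
    value = as.vector(lf$abundance))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Average a maturity ogive over its final years
#'
#' Maturity is assumed constant in time and taken as the per-length
#' unweighted mean over the final `last_n` years, clipped to `[0, 1]`.
#'
#' @param ogive_by_year data.frame with columns `year`, `length_lower`,
#'   `value`.
#' @param last_n number of final years to average (default 3).
#' @return data.frame with columns `length_lower`, `value`.
#' @export
prepare_maturity <- function(ogive_by_year, last_n = 3) {
  need <- c("year", "length_lower", "value")
  stopifnot(all(need %in% names(ogive_by_year)))
  years <- sort(unique(ogive_by_year$year))
  if (length(years) < last_n)
    stop("fewer years than last_n in the maturity ogive")
  keep <- ogive_by_year$year %in% utils::tail(years, last_n)
  sub <- ogive_by_year[keep, ]
  agg <- stats::aggregate(value ~ length_lower, data = sub, FUN = mean)
  agg$value <- pmin(pmax(agg$value, 0), 1)
  agg[order(agg$length_lower), c("length_lower", "value")]
}

#' Read a pipeline configuration file
#'
#' YAML configuration with defaults filled in for absent keys; see the
#' package vignette for the schema (growth marginals and copula,
#' mortality models, slicing, assessment grid and fit settings, ensemble
#' settings, iteration count, seed).
#'
#' @param path YAML file path (NULL returns pure defaults).
#' @return Nested list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    n_iterations = 25,
    seed = 1,
    growth = list(linf_median = 130, linf_cv = 0.10,
                  k_median = 0.164, k_cv = 0.10,
                  t0_min = -0.184, t0_max = 0,
                  z = 1.96, copula_df = 4,
                  correlation = as.vector(default_growth_correlation())),
    mortality = list(models = c("constant", "gislason"),
                     constant_value = 0.4,
                     jensen_window = c(15, 60)),
    slicing = list(plusgroup_threshold = 0.95),
    scaa = list(fbar_range = c(1, 3), grid = "full",
                est_uncertainty = TRUE, maxit = 400),
    ensemble = list(alpha = 0.05, n_boot = 2000, n_select = NULL,
                    min_iterations = 10, quantiles = c(0.1, 0.5, 0.9))
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  .merge_config(defaults, user)
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.write_input_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_length_table(bundle$catch, file.path(dir, "catch.csv"))
  for (s in seq_along(bundle$indices)) {
    write_length_table(bundle$indices[[s]],
                       file.path(dir, sprintf("index%d.csv", s)))
  }
  utils::write.csv(bundle$maturity, file.path(dir, "maturity.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  timings <- vapply(bundle$indices, function(ix)
    attr(ix, "timing") %||% 0, numeric(1))
  yaml::write_yaml(list(seed = bundle$seed, survey_timing = timings),
                   file.path(dir, "inputs.yml"))
  invisible(dir)
}

#' Write a growth ensemble as a table
#'
#' Three-column CSV (`linf`, `k`, `t0`), one row per iteration.
#'
#' @param ensemble a `growth_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "growth_ensemble"))
  utils::write.csv(ensemble$draws, path, row.names = FALSE)
  invisible(path)
}

#' Read a growth ensemble table
#'
#' @param path CSV with columns `linf`, `k`, `t0`.
#' @param seed seed metadata to attach (the file itself is
#'   deterministic).
#' @return A `growth_ensemble`.
#' @export
read_growth_ensemble <- function(path, seed = NA_integer_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("linf", "k", "t0") %in% names(df)))
  structure(list(draws = df[, c("linf", "k", "t0")], seed = seed),
            class = "growth_ensemble")
}

#' Serialize fit-grid results as a long table
#'
#' @param variants list of `model_variant` objects.
#' @return Long data.frame (variant metadata, iteration, year, quantity,
#'   value).
#' @export
variants_to_table <- function(variants) {
  rows <- list()
  for (v in variants) {
    for (j in seq_along(v$summaries)) {
      s <- v$summaries[[j]]
      for (q in c("recruitment", "ssb", "fbar", "catch", "harvest_rate")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sa_config_id = v$sa_config_id,
          mortality_model = v$mortality_model,
          iteration = v$iteration_ids[j],
          year = s$year, quantity = q, value = s[[q]])
      }
    }
  }
  do.call(rbind, rows)
}
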