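# build a synthetic variant whose final-year harvest rates follow `hr`
fake_variant <- function(id, hr, gcv = NULL, mortality = "constant") {
  summaries <- lapply(hr, function(h)
    data.frame(year = 1:3, recruitment = 1, ssb = 1, fbar = 0.2,
               catch = 1, harvest_rate = c(0.1, 0.1, h)))
  if (is.null(gcv)) gcv <- rep(1, length(hr))
  model_variant(id, mortality, summaries, gcv)
}

test_that("variant filtering rejects two-cluster harvest rates", {
  set.seed(21)
  uni <- fake_variant(1, rlnorm(80, log(0.2), 0.2))
  bi <- fake_variant(2, c(rnorm(40, 0.05, 0.003), rnorm(40, 0.6, 0.003)))
  tiny <- fake_variant(3, runif(5))
  out <- filter_variants(list(uni, bi, tiny), n_boot = 400, seed = 2,
                         min_iterations = 10)
  expect_equal(out$report$rejected, c(FALSE, TRUE, TRUE))
  expect_match(out$report$reason[3], "insufficient")
  expect_length(out$retained, 1L)
  expect_equal(out$retained[[1]]$sa_config_id, 1)
  empty <- filter_variants(list())
  expect_length(empty$retained, 0L)
  expect_equal(nrow(empty$report), 0L)
})

test_that("GCV weights are inverse-median, normalised and scale free", {
  v1 <- fake_variant(1, runif(20), gcv = rep(1, 20))
  v2 <- fake_variant(2, runif(20), gcv = rep(3, 20))
  w <- gcv_weights(list(v1, v2))
  expect_equal(w, c(0.75, 0.25))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # equal medians -> equal weights; single variant -> weight 1
  expect_equal(gcv_weights(list(v1, v1)), c(0.5, 0.5))
  expect_equal(gcv_weights(list(v2)), 1)
  # invariant to rescaling all GCVs
  v1s <- fake_variant(1, runif(20), gcv = rep(1 * 273.5, 20))
  v2s <- fake_variant(2, runif(20), gcv = rep(3 * 273.5, 20))
  expect_equal(gcv_weights(list(v1s, v2s)), w, tolerance = 1e-12)
  bad <- fake_variant(1, runif(5), gcv = c(1, -1, 2, 1, 1))
  expect_error(gcv_weights(list(bad)), "positive")
  expect_equal(best_variant(list(v1, v2))$sa_config_id, 1)
})

test_that("model averaging samples variants by weight without reuse", {
  set.seed(3)
  v1 <- fake_variant(1, runif(40), gcv = rep(1, 40))
  v2 <- fake_variant(2, runif(30), gcv = rep(2, 30))
  w <- gcv_weights(list(v1, v2))
  ens <- model_average(list(v1, v2), w, n_select = 30, seed = 9)
  expect_length(ens$summaries, 30L)
  # provenance pairs unique; per-variant counts within capacity
  key <- paste(ens$provenance$variant, ens$provenance$iteration)
  expect_equal(anyDuplicated(key), 0L)
  counts <- table(factor(ens$provenance$variant, levels = 1:2))
  expect_lte(counts[[1]], 40)
  expect_lte(counts[[2]], 30)
  # reproducible under seed
  ens2 <- model_average(list(v1, v2), w, n_select = 30, seed = 9)
  expect_identical(ens$provenance, ens2$provenance)
  # n_select above the minimum errors
  expect_error(model_average(list(v1, v2), w, n_select = 31), "exceed")
  # degenerate weights select only the supported variant
  ens0 <- model_average(list(v1, v2), c(1, 0), n_select = 10, seed = 1)
  expect_true(all(ens0$provenance$variant == 1))
})

test_that("selection frequencies converge to the weights", {
  v1 <- fake_variant(1, runif(50), gcv = rep(1, 50))
  v2 <- fake_variant(2, runif(50), gcv = rep(3, 50))
  v3 <- fake_variant(3, runif(50), gcv = rep(2, 50))
  vars <- list(v1, v2, v3)
  w <- gcv_weights(vars)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(77)
  picks <- integer(3)
  for (r in 1:250) {
    ens <- model_average(vars, w, n_select = 40, seed = r)
    picks <- picks + tabulate(ens$provenance$variant, 3)
  }
  freq <- picks / sum(picks)
  expect_lt(max(abs(freq - w)), 0.02)
})

test_that("ensemble quantile summaries behave", {
  v <- fake_variant(1, c(0.1, 0.2, 0.3))
  ens <- model_average(list(v), 1, n_select = 3, seed = 1)
  sm <- summarize_ensemble(ens, quantiles = c(0.1, 0.5, 0.9))
  med <- sm$value[sm$quantity == "harvest_rate" & sm$quantile == 0.5]
  expect_equal(med[3], 0.2)
  # quantiles monotone in probability
  for (q in unique(sm$quantity)) {
    sub <- sm[sm$quantity == q & sm$year == 3, ]
    expect_true(all(diff(sub$value[order(sub$quantile)]) >= 0))
  }
  # single iteration: all quantiles equal that series
  one <- model_average(list(fake_variant(1, 0.4)), 1, n_select = 1,
                       seed = 1)
  sm1 <- summarize_ensemble(one)
  expect_equal(unique(sm1$value[sm1$quantity == "ssb"]), 1)
})
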