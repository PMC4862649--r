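test_that("age assignment floors the inverse growth curve and clamps", {
  p <- growth_params(130, 0.164, -0.092)
  # 65 cm maps to floor(4.13) = 4
  expect_equal(assign_ages(65, p), 4L)
  mids <- c(0.5, 10, 65, 120, 129.5, 140)
  ages <- assign_ages(mids, p)
  expect_true(all(diff(ages) >= 0))
  expect_gte(min(ages), 0L)
  # beyond-linf classes get oldest finite age + 1
  expect_equal(ages[6], max(ages[1:5]) + 1L)
  # classes in the same age interval share a label
  expect_equal(assign_ages(c(64, 65), p), c(4L, 4L))
})

test_that("plusgroup is the smallest age reaching the biomass share", {
  b <- stats::setNames(c(0.5, 0.3, 0.15, 0.05), 0:3)
  expect_equal(compute_plusgroup(b, 0.95), 2L)
  expect_equal(compute_plusgroup(b, 1.0), 3L)
  expect_equal(compute_plusgroup(stats::setNames(5, 7), 0.2), 7L)
  expect_error(compute_plusgroup(stats::setNames(c(0, 0), 0:1), 0.95))
})

test_that("weighted aggregation follows the slicing rules", {
  # two classes mapped to one age: abundances (10, 30), weights (1, 2)
  out <- scaaens:::.slice_year(c(0L, 0L), 0L, c(10, 30), c(1, 2),
                               c(0.5, 0.4), c(0.1, 0.3))
  expect_equal(out$wt, 1.75)         # abundance-weighted
  expect_equal(out$m, 0.45)          # unweighted mean
  expect_equal(out$mat, 0.2)
  expect_equal(out$catch, 40)
})

test_that("slicing conserves abundance and biomass on randomized fixtures", {
  for (seed in 1:12) {
    fx <- random_length_inputs(seed)
    st <- slice_stock(fx$lf, fx$wl, fx$m_curve, fx$maturity, fx$growth)
    wt_len <- weight_at_length(midpoints(fx$lf), fx$wl)
    tot_n <- colSums(fx$lf$abundance)
    tot_b <- colSums(fx$lf$abundance * wt_len)
    for (it in st$iterations) {
      expect_lt(max(abs(colSums(it$catch_n) - tot_n) / tot_n), 1e-9)
      expect_lt(max(abs(colSums(it$catch_n * it$weight) - tot_b) / tot_b),
                1e-9)
      expect_true(all(it$maturity >= 0 & it$maturity <= 1))
      expect_true(all(it$m > 0))
    }
  }
})

test_that("per-iteration plusgroups differ across growth draws", {
  om <- operating_model()
  sim <- simulate_population(om, 1)
  lf <- render_lengths(sim$catch_n, om)
  growth <- sample_growth_params(table2_marginals(), default_copula(),
                                 n = 25, seed = 3)
  mids <- midpoints(lf)
  mc <- build_mortality_ensemble("gislason", mids, growth)
  st <- slice_stock(lf, weight_length_params(), mc,
                    stats::plogis((mids - 45) / 6), growth)
  pg <- vapply(st$iterations, `[[`, 1L, "plusgroup")
  expect_gt(length(unique(pg)), 1L)
  expect_true(all(pg >= 1L))
})

test_that("index slicing shares growth draws and conserves totals", {
  om <- operating_model()
  sim <- simulate_population(om, 2)
  growth <- sample_growth_params(table2_marginals(), default_copula(),
                                 n = 5, seed = 9)
  idx <- render_surveys(sim, seed = 2)[[1]]
  ai <- slice_index(idx, growth, plusgroup = c(6L, 8L, 9L, 7L, 10L),
                    timing = attr(idx, "timing"))
  expect_equal(ai$n_iter, 5L)
  tot <- colSums(idx$abundance)
  for (i in 1:5) {
    expect_equal(nrow(ai$iterations[[i]]), c(6L, 8L, 9L, 7L, 10L)[i] + 1L)
    expect_lt(max(abs(colSums(ai$iterations[[i]]) - tot) / tot), 1e-9)
  }
  # all mass in one class lands in a single age
  one <- length_frequency(c(31, 33), 2, 2001, matrix(c(0, 50), 2, 1))
  ai1 <- slice_index(one, growth, plusgroup = 10L)
  expect_equal(sum(ai1$iterations[[1]] > 0), 1L)
})

test_that("weight-length evaluation matches the power law", {
  wl <- weight_length_params()
  expect_equal(weight_at_length(50, wl), 6.59e-5 * 50^3.01721,
               tolerance = 1e-12)
  expect_equal(weight_at_length(50, wl), 8.811, tolerance = 1e-3)
})
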