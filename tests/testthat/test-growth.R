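test_that("triangle bounds from cv reproduce the reference growth bounds", {
  bl <- triangle_bounds_from_cv(130, 0.10, 1.96)
  expect_equal(unname(bl), c(104.520, 155.480), tolerance = 1e-12)
  bk <- triangle_bounds_from_cv(0.164, 0.10, 1.96)
  expect_equal(unname(bk), c(0.131856, 0.196144), tolerance = 1e-12)
  expect_equal(round(unname(bk), 3), c(0.132, 0.196))
  expect_equal(unname(triangle_bounds_from_cv(10, 0, 1.96)), c(10, 10))
  expect_error(triangle_bounds_from_cv(10, -0.1), "non-negative")
})

test_that("triangle quantile inverts the piecewise-quadratic CDF", {
  tri <- triangle_marginal(0, 1, 2)
  expect_equal(triangle_quantile(0, tri), 0)
  expect_equal(triangle_quantile(0.5, tri), 1)
  # rising limb: F(x) = x^2/2 on [0,1], so F(0.5) = 0.125
  expect_equal(triangle_quantile(0.125, tri), 0.5)
  expect_error(triangle_quantile(1.2, tri), "\\[0, 1\\]")
  # quantile agrees with brute-force CDF grid inversion
  set.seed(1)
  for (case in 1:100) {
    lo <- runif(1, -5, 0); up <- lo + runif(1, 0.5, 10)
    md <- runif(1, lo, up)
    m <- triangle_marginal(lo, md, up)
    u <- runif(1)
    grid <- seq(lo, up, length.out = 1e5)
    brute <- grid[which.max(triangle_cdf(grid, m) >= u)]
    expect_equal(triangle_quantile(u, m), brute, tolerance = 1e-3)
    expect_equal(triangle_cdf(triangle_quantile(u, m), m), u,
                 tolerance = 1e-6)
  }
})

test_that("t-copula growth sampling respects bounds, seed and rank signs", {
  marg <- table2_marginals()
  cop <- default_copula()
  ge <- sample_growth_params(marg, cop, n = 2000, seed = 7)
  expect_equal(nrow(ge$draws), 2000)
  expect_true(all(ge$draws$linf >= marg$linf$lower &
                    ge$draws$linf <= marg$linf$upper))
  expect_true(all(ge$draws$k >= marg$k$lower & ge$draws$k <= marg$k$upper))
  expect_true(all(ge$draws$t0 >= marg$t0$lower & ge$draws$t0 <= 0))
  ge2 <- sample_growth_params(marg, cop, n = 2000, seed = 7)
  expect_identical(ge$draws, ge2$draws)
  # rank-correlation signs follow the copula correlation signs
  expect_lt(cor(ge$draws$linf, ge$draws$k, method = "spearman"), 0)
  expect_gt(cor(ge$draws$k, ge$draws$t0, method = "spearman"), 0)
})

test_that("sampled marginals match the triangle CDF (KS distance)", {
  marg <- table2_marginals()
  ge <- sample_growth_params(marg, default_copula(), n = 5000, seed = 3)
  for (nm in c("linf", "k", "t0")) {
    x <- sort(ge$draws[[nm]])
    ks <- max(abs(triangle_cdf(x, marg[[nm]]) - seq_along(x) / length(x)))
    expect_lt(ks, 0.05)
  }
})

test_that("copula input is scale invariant (unscaled covariance allowed)", {
  corr <- default_growth_correlation()
  sds <- c(13, 0.016, 0.05)
  cov_big <- 37.3 * (corr * tcrossprod(sds))
  g1 <- sample_growth_params(table2_marginals(), copula_spec(corr), 500, 5)
  g2 <- sample_growth_params(table2_marginals(), copula_spec(cov_big), 500, 5)
  expect_equal(g1$draws, g2$draws)
})

test_that("invalid copula matrices are rejected", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(copula_spec(bad), "positive definite")
  asym <- default_growth_correlation(); asym[1, 2] <- 0.2
  expect_error(copula_spec(asym), "symmetric")
})

test_that("von Bertalanffy curve and its inverse are a consistent pair", {
  p <- growth_params(130, 0.164, -0.092)
  expect_equal(vb_length_at_age(p$t0, p), 0)
  expect_error(vb_length_at_age(p$t0 - 0.1, p), ">= t0")
  expect_equal(vb_age_at_length(0, p), p$t0)
  # L = linf/2 solves to t0 - log(0.5)/k
  expect_equal(vb_age_at_length(65, p), -0.092 - log(0.5) / 0.164,
               tolerance = 1e-12)
  expect_equal(vb_age_at_length(65, p), 4.1345, tolerance = 1e-5)
  p0 <- growth_params(100, 0.3, 0)
  expect_equal(vb_age_at_length(100 * (1 - exp(-0.3)), p0), 1,
               tolerance = 1e-12)
  for (L in c(1, 10, 64.9, 129)) {
    expect_equal(vb_length_at_age(vb_age_at_length(L, p), p), L,
                 tolerance = 1e-10)
  }
  ages <- seq(0, 60, by = 0.5)
  lens <- vb_length_at_age(ages, p)
  expect_true(all(diff(lens) > 0))
  expect_lt(max(lens), p$linf)
  expect_error(vb_age_at_length(130, p), "below linf")
})
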