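test_that("link functions reproduce the reference worked values", {
  # season-1 / site-1 baseline posterior means
  expect_equal(monthly_survival(25, -0.817, -0.048), 0.88, tolerance = 0.02)
  expect_equal(monthly_survival(45, -0.817, -0.048), 0.95, tolerance = 0.01)
  expect_equal(recapture_prob(25, -2.120, 0.031), 0.21, tolerance = 0.02)
  expect_equal(recapture_prob(45, -2.120, 0.031), 0.33, tolerance = 0.02)
  expect_equal(expected_eggs(43, -3.157, 0.250), 7.593, tolerance = 1e-3)
  expect_equal(expected_eggs(47, -3.157, 0.250), 8.593, tolerance = 1e-3)
  expect_equal(growth_mean(25, 0.473, 43.461), 31.957, tolerance = 1e-3)
  expect_equal(growth_variance(25, 2.936, -0.052), 1.636, tolerance = 1e-6)
})

test_that("growth map is a contraction with fixed point at L", {
  K <- 0.473; L <- 43.461
  expect_equal(growth_mean(L, K, L), L)
  expect_equal(growth_mean(L, 2.5, L), L)
  for (x in c(0, 10, 25, 40, 60)) {
    expect_equal(abs(growth_mean(x, K, L) - L), exp(-K) * abs(x - L))
  }
  # vanishing growth rate leaves size unchanged
  expect_equal(growth_mean(30, 1e-10, L), 30, tolerance = 1e-7)
})

test_that("growth variance floors at eps and hits the intercept at x = 0", {
  expect_equal(growth_variance(0, 2.936, -0.052), 2.936)
  # line is negative above ~56 mm at the reference coefficients
  expect_equal(growth_variance(60, 2.936, -0.052), 0.1)
  expect_equal(growth_variance(60, 2.936, -0.052, floor = 0.25), 0.25)
  expect_gt(min(growth_variance(seq(0, 80, 0.5), 2.936, -0.052)), 0)
})

test_that("interval survival composes multiplicatively and respects the grid", {
  e <- -0.817; f <- -0.048
  expect_equal(interval_survival(30, e, f, 1), monthly_survival(30, e, f))
  for (x in c(20, 35, 50)) {
    expect_equal(interval_survival(x, e, f, 1.5 + 2.5),
                 interval_survival(x, e, f, 1.5) * interval_survival(x, e, f, 2.5))
    expect_equal(interval_survival(x, e, f, 2.5),
                 interval_survival(x, e, f, 0.5)^5)
  }
  expect_equal(interval_survival(45, e, f, 12),
               monthly_survival(45, e, f)^12)
  expect_equal(interval_survival(45, e, f, 12), 0.543, tolerance = 5e-3)
  expect_error(interval_survival(30, e, f, 0.3), "0.5")
  expect_error(interval_survival(30, e, f, -1))
})

test_that("survival is monotone in size with sign opposite to the slope", {
  x <- seq(5, 60, 0.5)
  expect_true(all(diff(monthly_survival(x, -0.8, -0.05)) > 0))
  expect_true(all(diff(monthly_survival(x, -0.8, 0.05)) < 0))
  s <- monthly_survival(x, -0.8, 0)
  expect_true(all(s == s[1]))
})

test_that("probability outputs stay strictly inside (0, 1)", {
  set.seed(4)
  for (rep in 1:40) {
    x <- runif(1, 0, 60)
    e <- runif(1, -2, 2); f <- runif(1, -0.05, 0.05)
    g <- runif(1, -4, 4); h <- runif(1, -0.1, 0.1)
    s <- monthly_survival(x, e, f)
    p <- recapture_prob(x, g, h)
    expect_true(s > 0 && s < 1)
    expect_true(p > 0 && p < 1)
  }
  expect_equal(recapture_prob(50, 0, 0), 0.5)
  expect_equal(monthly_survival(50, -0.8, 0), exp(-exp(-0.8)))
})

test_that("fecundity and maturity rules behave at their boundaries", {
  expect_equal(expected_eggs(60, -3.157, 0), 0)      # negative line clamps
  expect_equal(expected_eggs(0, 2, 0.1), 2)
  expect_equal(expected_eggs(5, -3.157, 0.25, clamp = FALSE), -1.907)
  expect_identical(reproduction_indicator(35.9), 0)
  expect_identical(reproduction_indicator(36), 1)
  expect_identical(reproduction_indicator(0, maturity_threshold = 0), 1)
})

test_that("invalid sizes and parameters are rejected", {
  expect_error(growth_mean(-1, 0.5, 40))
  expect_error(growth_mean(NA_real_, 0.5, 40))
  expect_error(growth_mean(25, -0.1, 40))
  expect_error(monthly_survival(Inf, -0.8, -0.05))
  expect_error(recapture_prob(-2, 0, 0))
})
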