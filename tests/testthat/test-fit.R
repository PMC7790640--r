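test_that("the sampler is deterministic given data and seed", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 17), tiny_design(60))
  f1 <- suppressWarnings(fit_cmr(d, chains = 2, iter = 600, burn = 300, thin = 3, seed = 4))
  f2 <- suppressWarnings(fit_cmr(d, chains = 2, iter = 600, burn = 300, thin = 3, seed = 4))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_cmr(d, chains = 2, iter = 600, burn = 300, thin = 3, seed = 5))
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(nrow(f1$draws), 2 * (600 - 300) / 3)
  expect_named(f1$rhat)
})

test_that("degenerate data without recaptures aborts with a message", {
  occ <- data.frame(site = 1, occasion = 1:4,
                    month_offset = c(0, 1, 12, 13), season = rep(1:2, each = 2))
  des <- survey_design(occ, n_initial = 3, staggered_frac = 0)
  rec <- data.frame(id = 1:3, site = 1L, occasion = 1L, month_offset = 0,
                    size_mm = c(30, 35, 40), eggs = NA_real_)
  d <- capture_data(rec, design = des)
  expect_error(fit_cmr(d), "recaptured")
})

test_that("posterior summaries follow their closed-form oracles", {
  set.seed(33)
  m <- cbind(const = rep(2.5, 10000), z = rnorm(10000))
  s <- summarize_draws(m)
  expect_equal(s$mean[1], 2.5)
  expect_equal(s$sd[1], 0)
  expect_equal(s$q2.5[1], 2.5)
  expect_equal(s$q97.5[1], 2.5)
  # standard-normal column: central 95% interval about +/- 1.96
  expect_equal(s$q2.5[2], -1.96, tolerance = 0.05)
  expect_equal(s$q97.5[2], 1.96, tolerance = 0.05)
  expect_equal(s$mean[2], 0, tolerance = 0.05)
})

test_that("the summary table carries every model parameter", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 18), tiny_design(60))
  f <- suppressWarnings(fit_cmr(d, chains = 2, iter = 400, burn = 200, thin = 2, seed = 6))
  s <- summarize_draws(f)
  expect_setequal(s$parameter, vital_rate_param_names())
  expect_true(all(is.finite(s$mean)))
  expect_true(all(s$q2.5 <= s$q97.5))
})

test_that("near-perfect detection drives the recapture intercept high", {
  p <- flat_params(monthly_surv = 0.97, p_detect = 0.995)
  d <- simulate_population(simulation_truth(p, seed = 19), tiny_design(150))
  f <- suppressWarnings(fit_cmr(d, chains = 2, iter = 1500, burn = 750, thin = 3, seed = 7))
  # posterior detection probability at a typical size concentrates near 1
  pd <- plogis(f$draws[, "rec_int"] + f$draws[, "rec_slp"] * 40)
  expect_gt(mean(pd), 0.9)
})

test_that("a reduced fit recovers the main rates from its own truth", {
  p <- ref_params()
  d <- simulate_population(simulation_truth(p, seed = 23),
                           default_survey_design(n_initial = c(250, 3, 3),
                                                 staggered_frac = 0.25))
  f <- suppressWarnings(fit_cmr(d, chains = 2, iter = 3000, burn = 1500, thin = 3,
                                seed = 8))
  s <- summarize_draws(f)
  for (par in c("K", "L", "haz_int", "haz_slp", "egg_slp")) {
    row <- s[s$parameter == par, ]
    expect_gt(p[[par]], row$q2.5)
    expect_lt(p[[par]], row$q97.5)
  }
})
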