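test_that("simulation is deterministic for a fixed truth", {
  tr <- simulation_truth(ref_params(), seed = 9)
  d1 <- simulate_population(tr, tiny_design(60))
  d2 <- simulate_population(tr, tiny_design(60))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_population(simulation_truth(ref_params(), seed = 10), tiny_design(60))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("degenerate rates put every individual on every occasion", {
  # survival ~ 1 (tiny hazard) and detection ~ 1
  p <- flat_params(monthly_surv = 1 - 1e-12, p_detect = 1 - 1e-9)
  d <- simulate_population(simulation_truth(p, seed = 3), tiny_design(40))
  expect_equal(length(unique(d$id)), 40)
  expect_true(all(table(d$id) == 6))
})

test_that("one-month survival fraction matches the truth within binomial bounds", {
  n <- 10000
  p <- flat_params(monthly_surv = 0.9, p_detect = 1 - 1e-9)
  d <- simulate_population(simulation_truth(p, seed = 21), one_interval_design(n))
  # perfect detection: survivors of the single 1-month interval are those
  # seen at occasion 2
  surv <- sum(d$occasion == 2) / n
  expect_lt(abs(surv - 0.9), 1.96 * sqrt(0.9 * 0.1 / n))
})

test_that("records never precede first detection and eggs imply maturity", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 5),
                           default_survey_design(n_initial = c(80, 80, 80)))
  expect_true(all(tapply(d$occasion, d$id, function(o) all(diff(o) > 0))))
  eg <- !is.na(d$eggs)
  expect_gt(sum(eg), 0)
  expect_true(all(d$size_mm[eg] >= 36))
  expect_setequal(unique(d$site), 1:3)
})

test_that("capture CSV round-trips byte-identically", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 6), tiny_design(50))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_capture_csv(d, f1)
  d2 <- read_capture_csv(f1, design = attr(d, "design"))
  write_capture_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)
})

test_that("empty capture data writes a header-only file", {
  empty <- capture_data(
    data.frame(id = integer(), site = integer(), occasion = integer(),
               month_offset = numeric(), size_mm = numeric(), eggs = numeric()),
    design = tiny_design(0))
  f <- tempfile(fileext = ".csv")
  write_capture_csv(empty, f)
  expect_length(readLines(f), 1L)
})

test_that("perfect-detection simulations recover the generating rates by regression", {
  # complete detection makes naive regressions consistent for the truth
  p <- ref_params()
  q <- c(unname(p)); names(q) <- names(p)
  q[c("rec_int", "rec_slp", "season2_rec_int", "season2_rec_slp",
      "site2_rec_int", "site3_rec_int")] <- c(15, 0, 0, 0, 0, 0)
  q <- as_vital_rate_params(q)
  d <- simulate_population(simulation_truth(q, seed = 31),
                           default_survey_design(n_initial = c(2000, 3, 3),
                                                 staggered_frac = 0))
  cmr <- prepare_cmr_data(d)
  ind <- cmr$individuals[cmr$individuals$site == 1, ]
  both <- ind[!is.na(ind$x1) & !is.na(ind$x2), ]
  fitg <- lm(x2 ~ x1, data = both)
  K_hat <- -log(coef(fitg)[[2]])
  L_hat <- coef(fitg)[[1]] / (1 - coef(fitg)[[2]])
  expect_equal(K_hat, p[["K"]], tolerance = 0.1)
  expect_equal(L_hat, p[["L"]], tolerance = 0.02)
  # egg regression recovers the size-fecundity line
  eg <- cmr$eggs[cmr$eggs$season == 1 & cmr$eggs$site == 1, ]
  fite <- lm(count ~ size, data = eg)
  expect_equal(coef(fite)[[2]], p[["egg_slp"]], tolerance = 0.25)
})
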