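test_that("two-occasion CJS terms match their closed forms", {
  # seen-seen over one interval: phi * p
  expect_equal(exp(cjs_history_loglik(c(1, 1), 1, phi = 0.9, p = c(0.3, 0.3))),
               0.27)
  # seen-unseen: dead, or alive and missed
  expect_equal(exp(cjs_history_loglik(c(1, 0), 1, phi = 0.9, p = c(0.3, 0.3))),
               (1 - 0.9) + 0.9 * (1 - 0.3))
})

test_that("CJS likelihood equals brute-force path enumeration on toy histories", {
  set.seed(11)
  for (rep in 1:60) {
    T <- sample(3:6, 1)
    phi <- runif(T - 1, 0.3, 0.98)
    p <- runif(T, 0.05, 0.9)
    first <- sample(1:(T - 1), 1)
    y <- integer(T); y[first] <- 1L
    later <- seq(first + 1, T)
    y[later] <- rbinom(length(later), 1, 0.5)
    ll <- cjs_history_loglik(y, first, phi, p)
    expect_equal(exp(ll), cjs_history_brute(y, first, phi, p), tolerance = 1e-12)
  }
})

test_that("joint likelihood decomposes additively over its components", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 8), tiny_design(70))
  cmr <- prepare_cmr_data(d)
  p <- ref_params()
  full <- joint_loglik(p, cmr)
  comps <- attr(full, "components")
  expect_equal(as.numeric(full), sum(comps))
  # dropping the egg records changes only the egg term
  cmr_noegg <- cmr
  cmr_noegg$eggs <- cmr$eggs[0, ]
  noegg <- joint_loglik(p, cmr_noegg)
  expect_equal(attr(noegg, "components")[["cjs"]], comps[["cjs"]])
  expect_equal(attr(noegg, "components")[["growth"]], comps[["growth"]])
  expect_equal(attr(noegg, "components")[["eggs"]], 0)
})

test_that("growth term at the asymptote is a normal density centred at L", {
  p <- ref_params()
  L <- p[["L"]]
  occ <- data.frame(site = 1, occasion = 1:4,
                    month_offset = c(0, 1, 12, 13), season = rep(1:2, each = 2))
  des <- survey_design(occ, n_initial = 1, staggered_frac = 0)
  x2_obs <- L + 0.7
  rec <- data.frame(id = 1L, site = 1L, occasion = c(1L, 3L),
                    month_offset = c(0, 12), size_mm = c(L, x2_obs),
                    eggs = NA_real_)
  cmr <- prepare_cmr_data(capture_data(rec, design = des))
  gl <- attr(joint_loglik(p, cmr), "components")[["growth"]]
  v <- growth_variance(L, p[["gv_int"]], p[["gv_slp"]])
  expect_equal(gl, dnorm(x2_obs, L, sqrt(v), log = TRUE))
})

test_that("doubling every interval squares every interval survival", {
  set.seed(12)
  x <- runif(10, 15, 55)
  dts <- sample(seq(0.5, 3, 0.5), 10, replace = TRUE)
  s1 <- interval_survival(x, -0.8, -0.04, dts)
  s2 <- interval_survival(x, -0.8, -0.04, 2 * dts)
  expect_equal(s2, s1^2)
})

test_that("compiled joint likelihood agrees with the reference implementation", {
  d <- simulate_population(simulation_truth(ref_params(), seed = 14),
                           default_survey_design(n_initial = c(60, 50, 50)))
  cmr <- prepare_cmr_data(d)
  packed <- sizedemog:::pack_cmr_for_cpp(cmr)
  set.seed(15)
  for (rep in 1:5) {
    p <- ref_params()
    q <- c(unname(p)) + rnorm(31, 0, 0.02 * pmax(abs(c(unname(p))), 0.2))
    names(q) <- names(p)
    q["K"] <- abs(q["K"]); q["egg_var"] <- abs(q["egg_var"])
    q <- as_vital_rate_params(q)
    lat <- vapply(which(cmr$individuals$latent_x2), function(i) {
      r <- resolve_vital_rates(q, cmr$individuals$site[i], 1)
      growth_mean(cmr$individuals$x1[i], r$K, r$L)
    }, numeric(1))
    llr <- as.numeric(joint_loglik(q, cmr, lat))
    llc <- sizedemog:::.joint_loglik_cpp(packed, c(unname(q)[1:30], log(q[["egg_var"]])), lat)
    expect_equal(llr, llc, tolerance = 1e-10)
  }
})
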