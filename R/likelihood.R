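#' Cormack-Jolly-Seber log-likelihood of one capture history
#'
#' Closed-form CJS likelihood conditional on first capture, with the latent
#' alive states marginalised: detected-interval terms up to the last
#' detection, then the probability of never being seen again computed by the
#' standard backward (chi) recursion.
#'
#' @param y 0/1 detection vector over all occasions at the individual's
#'   site (1 at the first capture).
#' @param first index of the first capture occasion.
#' @param phi survival probabilities over intervals `j -> j+1`
#'   (length `length(y) - 1`).
#' @param p detection probabilities at each occasion (only entries after
#'   `first` are used).
#' @return Log-likelihood of the history.
#' @export
cjs_history_loglik <- function(y, first, phi, p) {
  T <- length(y)
  stopifnot(length(phi) == T - 1, length(p) == T, y[first] == 1)
  last <- max(which(y == 1))
  ll <- 0
  if (last > first) {
    for (j in first:(last - 1)) {
      ll <- ll + log(phi[j]) +
        if (y[j + 1] == 1) log(p[j + 1]) else log(1 - p[j + 1])
    }
  }
  # chi_t: P(never detected after occasion t | alive at t)
  chi <- 1
  if (last < T) {
    for (j in (T - 1):last) chi <- (1 - phi[j]) + phi[j] * (1 - p[j + 1]) * chi
  }
  ll + log(chi)
}

#' Brute-force CJS likelihood by path enumeration
#'
#' Independent check of [cjs_history_loglik()]: sums the probability of the
#' observed history over every consistent latent death time (alive through
#' occasion `d`, dead afterwards). Exponential-free and exact; intended for
#' short (toy) histories.
#'
#' @inheritParams cjs_history_loglik
#' @return Likelihood (not log) of the history.
#' @export
cjs_history_brute <- function(y, first, phi, p) {
  T <- length(y)
  last <- max(which(y == 1))
  tot <- 0
  for (d in last:T) {  # d = last occasion alive
    pr <- 1
    if (d > first) for (j in first:(d - 1)) pr <- pr * phi[j]
    if (d < T) pr <- pr * (1 - phi[d])
    if (d > first) {
      for (j in (first + 1):d) pr <- pr * if (y[j] == 1) p[j] else (1 - p[j])
    }
    tot <- tot + pr
  }
  tot
}

ind_rates <- function(params, site, seasons, sizes_by_season, times) {
  # per-occasion detection prob and per-interval survival for one individual
  Tocc <- length(times)
  x_occ <- ifelse(seasons == 1, sizes_by_season[1], sizes_by_season[2])
  p <- phi <- numeric(Tocc)
  r <- list(resolve_vital_rates(params, site, 1),
            resolve_vital_rates(params, site, 2))
  for (j in seq_len(Tocc)) {
    rj <- r[[seasons[j]]]
    p[j] <- recapture_prob(x_occ[j], rj$rec_int, rj$rec_slp)
    if (j < Tocc) {
      phi[j] <- interval_survival(x_occ[j], rj$haz_int, rj$haz_slp,
                                  times[j + 1] - times[j])
    }
  }
  list(phi = phi[-Tocc], p = p)
}

#' Joint log-likelihood of the demographic model
#'
#' Sum of the three data components given the parameters and the latent
#' season-2 sizes: (i) CJS capture-history terms with size-dependent
#' survival (log-log hazard, interval exponents on the half-month grid) and
#' recapture (logit); (ii) Gaussian von Bertalanffy growth terms for every
#' individual with a season-1 size, using the observed or latent season-2
#' size; (iii) Gaussian egg-count terms. Site and season offsets are applied
#' per record. This is the reference implementation the MCMC sampler's
#' compiled likelihood is tested against.
#'
#' @param params a [vital_rate_params] object.
#' @param cmr a `cmr_data` object from [prepare_cmr_data()].
#' @param latent_x2 numeric vector of season-2 sizes for the individuals
#'   flagged `latent_x2` in `cmr$individuals` (in that order). Defaults to
#'   the growth-model expectation.
#' @param parts character subset of `c("cjs", "growth", "eggs")`.
#' @return Total log-likelihood with attribute `components`.
#' @export
joint_loglik <- function(params, cmr, latent_x2 = NULL,
                         parts = c("cjs", "growth", "eggs")) {
  params <- as_vital_rate_params(params)
  ind <- cmr$individuals
  occ_by_site <- split(cmr$design$occasions, cmr$design$occasions$site)
  lat_idx <- which(ind$latent_x2)
  if (is.null(latent_x2)) {
    latent_x2 <- vapply(lat_idx, function(i) {
      r <- resolve_vital_rates(params, ind$site[i], 1)
      growth_mean(ind$x1[i], r$K, r$L)
    }, numeric(1))
  }
  stopifnot(length(latent_x2) == length(lat_idx))
  x2 <- ind$x2
  x2[lat_idx] <- latent_x2

  ll_cjs <- ll_growth <- ll_eggs <- 0
  if ("cjs" %in% parts) {
    for (i in seq_len(nrow(ind))) {
      occ <- occ_by_site[[as.character(ind$site[i])]]
      xs <- c(ind$x1[i], x2[i])
      # an individual first seen in season 2 never uses its (absent) x1
      if (is.na(xs[1])) xs[1] <- 0
      rt <- ind_rates(params, ind$site[i], occ$season, xs, occ$month_offset)
      ll_cjs <- ll_cjs + cjs_history_loglik(cmr$det[[i]], ind$first[i],
                                            rt$phi, rt$p)
    }
  }
  if ("growth" %in% parts) {
    gi <- which(ind$has_growth)
    for (i in gi) {
      r <- resolve_vital_rates(params, ind$site[i], 1)
      m <- growth_mean(ind$x1[i], r$K, r$L)
      v <- growth_variance(ind$x1[i], r$gv_int, r$gv_slp)
      ll_growth <- ll_growth + stats::dnorm(x2[i], m, sqrt(v), log = TRUE)
    }
  }
  if ("eggs" %in% parts && nrow(cmr$eggs)) {
    for (k in seq_len(nrow(cmr$eggs))) {
      e <- cmr$eggs[k, ]
      r <- resolve_vital_rates(params, e$site, e$season)
      mu <- r$egg_int + r$egg_slp * e$size
      ll_eggs <- ll_eggs + stats::dnorm(e$count, mu, sqrt(r$egg_var), log = TRUE)
    }
  }
  structure(ll_cjs + ll_growth + ll_eggs,
            components = c(cjs = ll_cjs, growth = ll_growth, eggs = ll_eggs))
}
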