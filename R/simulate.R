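#' Simulate capture histories under the study design
#'
#' Individual-based forward simulation of the estimation model: each
#' individual carries one latent size per field season (within-season growth
#' is not modelled, matching the seasonal averaging used at estimation time),
#' survives each inter-occasion interval with the monthly survival raised to
#' the interval length, is detected at each occasion it is alive with the
#' size-dependent recapture probability, and advances in size between seasons
#' by von Bertalanffy growth plus Gaussian noise. Mature females (latent
#' seasonal size at or above the maturity threshold) carry an egg count drawn
#' from a rounded, zero-truncated normal around the linear size-fecundity
#' expectation; the count is recorded at the first occasion the female is
#' detected within that season. Only detected records are returned; the
#' generating truth stays attached as an attribute.
#'
#' @param truth a [simulation_truth] object.
#' @param design a [survey_design] object.
#' @return A `capture_data` object: data frame with columns `id`, `site`,
#'   `occasion`, `month_offset`, `size_mm`, `eggs` (NA when no eggs were
#'   counted), one row per detection, with the design and truth attached as
#'   attributes.
#' @export
simulate_population <- function(truth, design = default_survey_design()) {
  stopifnot(inherits(truth, "simulation_truth"), inherits(design, "survey_design"))
  set.seed(truth$seed)
  p <- truth$params
  fx <- truth$fixed
  mix <- design$init_mix
  out <- list()
  next_id <- 1L
  for (si in seq_along(sort(unique(design$occasions$site)))) {
    occ <- design$occasions[design$occasions$site == si, ]
    tms <- occ$month_offset
    seas <- occ$season
    Tocc <- nrow(occ)
    first_s2 <- match(2, seas)
    n <- design$n_initial[si]
    if (n == 0) next
    r1 <- resolve_vital_rates(p, site = si, season = 1)
    r2 <- resolve_vital_rates(p, site = si, season = 2)

    entry <- ifelse(stats::runif(n) < design$staggered_frac, first_s2, 1L)
    draw_init <- function(k) {
      juv <- stats::runif(k) < mix$juvenile_frac
      ifelse(juv,
             stats::rnorm(k, mix$juvenile_mean, sqrt(mix$juvenile_var)),
             stats::rnorm(k, mix$adult_mean, sqrt(mix$adult_var)))
    }
    x_entry <- pmax(draw_init(n), 10)
    # one latent size per season: entrants at occasion 1 grow into season 2
    x1 <- ifelse(entry == 1L, x_entry, NA_real_)
    x2 <- ifelse(entry == 1L,
                 growth_mean(x_entry, r1$K, r1$L) +
                   stats::rnorm(n, 0, sqrt(growth_variance(x_entry, r1$gv_int, r1$gv_slp))),
                 x_entry)
    x2 <- pmax(x2, 5)

    egg_count <- function(x, r) {
      mu <- expected_eggs(x, r$egg_int, r$egg_slp)
      pmax(round(stats::rnorm(length(x), mu, sqrt(r$egg_var))), 0)
    }
    eggs1 <- rep(NA_real_, n)
    sel1 <- !is.na(x1) & x1 >= fx$maturity_threshold
    eggs1[sel1] <- egg_count(x1[sel1], r1)
    eggs2 <- rep(NA_real_, n)
    sel2 <- x2 >= fx$maturity_threshold
    eggs2[sel2] <- egg_count(x2[sel2], r2)

    alive <- matrix(FALSE, n, Tocc)
    for (i in seq_len(n)) alive[i, entry[i]] <- TRUE
    for (j in seq_len(Tocc - 1)) {
      act <- which(alive[, j])
      if (length(act)) {
        dt <- tms[j + 1] - tms[j]
        # covariate and season parameters follow the interval's starting occasion
        r <- if (seas[j] == 1) r1 else r2
        xs <- if (seas[j] == 1) x1[act] else x2[act]
        sv <- interval_survival(xs, r$haz_int, r$haz_slp, dt)
        alive[act, j + 1] <- stats::runif(length(act)) < sv
      }
      ent <- which(entry == j + 1L)
      if (length(ent)) alive[ent, j + 1] <- TRUE
    }

    det <- matrix(FALSE, n, Tocc)
    for (j in seq_len(Tocc)) {
      act <- which(alive[, j])
      if (!length(act)) next
      r <- if (seas[j] == 1) r1 else r2
      xs <- if (seas[j] == 1) x1[act] else x2[act]
      pd <- recapture_prob(xs, r$rec_int, r$rec_slp)
      det[act, j] <- stats::runif(length(act)) < pd
    }

    for (i in which(rowSums(det) > 0)) {
      js <- which(det[i, ])
      sz_lat <- ifelse(seas[js] == 1, x1[i], x2[i])
      sz_obs <- sz_lat + if (truth$measurement_sd > 0)
        stats::rnorm(length(js), 0, truth$measurement_sd) else 0
      eg <- rep(NA_real_, length(js))
      for (s in 1:2) {
        in_s <- which(seas[js] == s)
        if (!length(in_s)) next
        cnt <- if (s == 1) eggs1[i] else eggs2[i]
        if (!is.na(cnt) && sz_obs[in_s[1]] >= fx$maturity_threshold)
          eg[in_s[1]] <- cnt
      }
      out[[length(out) + 1L]] <- data.frame(
        id = next_id, site = si, occasion = js,
        month_offset = tms[js], size_mm = sz_obs, eggs = eg)
      next_id <- next_id + 1L
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(), site = integer(), occasion = integer(),
               month_offset = numeric(), size_mm = numeric(), eggs = numeric())
  rownames(df) <- NULL
  capture_data(df, design = design, truth = truth)
}
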