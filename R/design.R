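#' Survey design for a cover-board capture-mark-recapture study
#'
#' Describes when each site was surveyed: one row per site x occasion with
#' the occasion's time as a month offset from the start of the study
#' (half-month precision) and the field season it belongs to. Also carries
#' the simulated initial cohort per site and the size distribution used to
#' seed it.
#'
#' @param occasions data frame with columns `site` (integer 1..3), `occasion`
#'   (1-based index within site), `month_offset` (months from study start,
#'   multiples of 0.5, strictly increasing within site) and `season` (1 or
#'   2, non-decreasing within site; at least 2 occasions per season).
#' @param n_initial integer vector, simulated cohort size per site.
#' @param init_mix list describing the initial size mixture:
#'   `juvenile_frac`, `juvenile_mean`, `juvenile_var`, `adult_mean`,
#'   `adult_var` (sizes in mm, variances in mm^2).
#' @param staggered_frac fraction of the simulated cohort that enters the
#'   study only at the first occasion of season 2 (new animals recruiting or
#'   surfacing between seasons); 0 seeds everyone at occasion 1.
#' @return A list of class `survey_design`.
#' @export
survey_design <- function(occasions,
                          n_initial = c(500, 450, 500),
                          init_mix = list(juvenile_frac = 0.2,
                                          juvenile_mean = 25, juvenile_var = 2,
                                          adult_mean = 40, adult_var = 16),
                          staggered_frac = 0.3) {
  stopifnot(is.data.frame(occasions),
            all(c("site", "occasion", "month_offset", "season") %in% names(occasions)))
  occasions <- occasions[order(occasions$site, occasions$occasion), ]
  check_month_grid(occasions$month_offset)
  for (s in unique(occasions$site)) {
    o <- occasions[occasions$site == s, ]
    if (any(diff(o$month_offset) <= 0))
      stop("occasion times must be strictly increasing within site ", s)
    if (any(diff(o$season) < 0))
      stop("season must be non-decreasing within site ", s)
    if (any(table(o$season) < 2))
      stop("need at least 2 occasions per season at site ", s)
  }
  sites <- sort(unique(occasions$site))
  stopifnot(length(n_initial) == length(sites), all(n_initial >= 0),
            staggered_frac >= 0, staggered_frac <= 1)
  structure(list(occasions = occasions, n_initial = n_initial,
                 init_mix = init_mix, staggered_frac = staggered_frac),
            class = "survey_design")
}

#' Default two-season, three-site survey design
#'
#' The design the simulator emulates: three cover-board sites surveyed on 6
#' occasions in field season 1 and 7, 7 and 8 occasions in season 2, with
#' occasions at least one month apart on the half-month grid and a summer
#' gap of 5-6 months between seasons.
#'
#' @inheritParams survey_design
#' @return A `survey_design` object.
#' @export
default_survey_design <- function(n_initial = c(500, 450, 500),
                                  staggered_frac = 0.3) {
  times <- list(
    `1` = list(s1 = c(0, 1, 2.5, 4, 5, 6.5),
               s2 = c(12, 13, 14.5, 15.5, 16.5, 17.5, 19)),
    `2` = list(s1 = c(0, 1, 3.5, 4.5, 5.5, 6.5),
               s2 = c(12, 13.5, 14.5, 15.5, 16.5, 18, 19)),
    `3` = list(s1 = c(0, 1, 3.5, 4.5, 6, 7),
               s2 = c(12, 13, 14, 15, 16, 17, 18, 19.5)))
  occ <- do.call(rbind, lapply(1:3, function(s) {
    t1 <- times[[s]]$s1; t2 <- times[[s]]$s2
    data.frame(site = s, occasion = seq_along(c(t1, t2)),
               month_offset = c(t1, t2),
               season = rep(1:2, c(length(t1), length(t2))))
  }))
  survey_design(occ, n_initial = n_initial, staggered_frac = staggered_frac)
}

check_month_grid <- function(m) {
  if (any(!is.finite(m)) || any(abs(m / 0.5 - round(m / 0.5)) > 1e-6)) {
    stop("month offsets must lie on the 0.5-month grid")
  }
  invisible(m)
}

#' Ground truth of a simulation
#'
#' Bundles the generating parameters with the seed so a simulated dataset can
#' be regenerated bit-identically and compared against its own truth in
#' parameter-recovery tests.
#'
#' @param params a [vital_rate_params] object used to generate the data.
#' @param fixed a [fixed_demography] object.
#' @param seed integer RNG seed.
#' @param measurement_sd per-capture measurement error SD on size, mm
#'   (default 0: observed size equals latent seasonal size).
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(params, fixed = fixed_demography(), seed = 1,
                             measurement_sd = 0) {
  structure(list(params = as_vital_rate_params(params), fixed = fixed,
                 seed = as.integer(seed), measurement_sd = measurement_sd),
            class = "simulation_truth")
}
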