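#' Canonical parameter names of the joint demographic model
#'
#' The joint model has 31 parameters: von Bertalanffy growth rate `K` and
#' asymptotic size `L` (with additive site offsets), intercept/slope of the
#' growth residual variance (`gv_*`, mm^2 and mm^2/mm, with site offsets on
#' both), intercept/slope of the expected egg count (`egg_*`, with season-2
#' and site-intercept offsets), intercept/slope of the log monthly mortality
#' hazard (`haz_*`, season-2 and site-intercept offsets), intercept/slope of
#' the logit recapture probability (`rec_*`, season-2 and site-intercept
#' offsets), and the egg-count residual variance `egg_var`.
#'
#' @return Character vector of parameter names in canonical order.
#' @export
vital_rate_param_names <- function() {
  c("K", "L", "site2_K", "site3_K", "site2_L", "site3_L",
    "gv_int", "gv_slp", "site2_gv_int", "site3_gv_int",
    "site2_gv_slp", "site3_gv_slp",
    "egg_int", "egg_slp", "season2_egg_int", "season2_egg_slp",
    "site2_egg_int", "site3_egg_int",
    "haz_int", "haz_slp", "season2_haz_int", "season2_haz_slp",
    "site2_haz_int", "site3_haz_int",
    "rec_int", "rec_slp", "season2_rec_int", "season2_rec_slp",
    "site2_rec_int", "site3_rec_int",
    "egg_var")
}

#' Construct a vital-rate parameter set
#'
#' Builds the full 31-parameter vector of the joint demographic model from
#' baseline values and (optional) additive site/season offsets. Baselines
#' refer to field season 1 at Site 1; offsets enter additively on the linear
#' predictor scale.
#'
#' @param K,L von Bertalanffy growth rate (1/yr) and asymptotic
#'   snout-to-vent length (mm); both must be positive after adding any site
#'   offset.
#' @param gv_int,gv_slp intercept (mm^2) and slope (mm^2/mm) of the linear
#'   model for growth residual variance.
#' @param egg_int,egg_slp intercept (eggs) and slope (eggs/mm) of the
#'   expected egg count.
#' @param haz_int,haz_slp intercept and size slope (1/mm) of the log monthly
#'   mortality hazard.
#' @param rec_int,rec_slp intercept and size slope (1/mm) of the logit
#'   recapture probability.
#' @param egg_var residual variance of the egg count (eggs^2), positive.
#' @param ... named additive offsets (e.g. `site2_K`, `season2_haz_int`);
#'   any offset named in [vital_rate_param_names()] is accepted, all others
#'   are rejected. Unspecified offsets default to 0.
#' @return A named numeric vector of class `vital_rate_params`.
#' @export
vital_rate_params <- function(K, L, gv_int, gv_slp, egg_int, egg_slp,
                              haz_int, haz_slp, rec_int, rec_slp,
                              egg_var = 4, ...) {
  nm <- vital_rate_param_names()
  p <- stats::setNames(numeric(length(nm)), nm)
  base <- c(K = K, L = L, gv_int = gv_int, gv_slp = gv_slp,
            egg_int = egg_int, egg_slp = egg_slp,
            haz_int = haz_int, haz_slp = haz_slp,
            rec_int = rec_int, rec_slp = rec_slp, egg_var = egg_var)
  p[names(base)] <- base
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nm)
    if (length(bad))
      stop("unknown parameter offset(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_vital_rate_params(structure(p, class = "vital_rate_params"))
}

validate_vital_rate_params <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  nm <- vital_rate_param_names()
  if (!all(nm %in% names(p))) {
    stop("missing parameter(s): ", paste(setdiff(nm, names(p)), collapse = ", "))
  }
  p <- structure(p[nm], class = "vital_rate_params")
  if (p[["L"]] <= 0) stop("asymptotic size L must be positive")
  for (s in c(0, p[["site2_K"]], p[["site3_K"]])) {
    if (p[["K"]] + s <= 0) stop("growth rate K must be positive at every site")
  }
  if (p[["egg_var"]] <= 0) stop("egg_var must be positive")
  p
}

#' @export
print.vital_rate_params <- function(x, ...) {
  cat("Vital-rate parameters (baseline = season 1, Site 1):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Coerce a named vector to a vital-rate parameter set
#'
#' @param x named numeric vector containing every name in
#'   [vital_rate_param_names()] (extra names are dropped).
#' @return A `vital_rate_params` object.
#' @export
as_vital_rate_params <- function(x) {
  validate_vital_rate_params(structure(as.numeric(x)[match(vital_rate_param_names(), names(x))],
                                       names = vital_rate_param_names(),
                                       class = "vital_rate_params"))
}

#' Resolve parameters for one site and season
#'
#' Adds the additive site and season offsets to the baseline coefficients and
#' returns the effective coefficients used by the vital-rate functions.
#' Growth (mean and variance) is season-independent; egg count, mortality
#' hazard and recapture carry season-2 offsets; sites 2 and 3 carry offsets
#' as estimated (intercept-and-slope for growth variance, intercept-only for
#' eggs/hazard/recapture, and offsets on both `K` and `L`).
#'
#' @param params a [vital_rate_params] object.
#' @param site site index, 1, 2 or 3.
#' @param season field season, 1 or 2.
#' @return Named list with elements `K`, `L`, `gv_int`, `gv_slp`, `egg_int`,
#'   `egg_slp`, `haz_int`, `haz_slp`, `rec_int`, `rec_slp`, `egg_var`.
#' @export
resolve_vital_rates <- function(params, site = 1, season = 1) {
  p <- as_vital_rate_params(params)
  stopifnot(site %in% 1:3, season %in% 1:2)
  off <- function(name) {
    if (site == 1) 0 else p[[paste0("site", site, "_", name)]]
  }
  s2 <- function(name) if (season == 2) p[[paste0("season2_", name)]] else 0
  list(
    K = p[["K"]] + off("K"),
    L = p[["L"]] + off("L"),
    gv_int = p[["gv_int"]] + off("gv_int"),
    gv_slp = p[["gv_slp"]] + off("gv_slp"),
    egg_int = p[["egg_int"]] + off("egg_int") + s2("egg_int"),
    egg_slp = p[["egg_slp"]] + s2("egg_slp"),
    haz_int = p[["haz_int"]] + off("haz_int") + s2("haz_int"),
    haz_slp = p[["haz_slp"]] + s2("haz_slp"),
    rec_int = p[["rec_int"]] + off("rec_int") + s2("rec_int"),
    rec_slp = p[["rec_slp"]] + s2("rec_slp"),
    egg_var = p[["egg_var"]]
  )
}

#' Fixed constants of the reproduction process
#'
#' Constants of the recruitment pathway that are not estimated from the
#' capture data but fixed from the literature on the study species: the
#' probability that an egg hatches, the probability a hatchling survives to
#' recruit at age 1, the size law of recruiting juveniles, the maturity
#' threshold, and the fraction of eggs producing daughters (the model tracks
#' females only).
#'
#' @param hatch_prob probability an egg hatches (default 0.9).
#' @param recruit_prob probability a hatchling recruits at age 1
#'   (default 0.574).
#' @param juvenile_size_mean mean size of recruiting juveniles, mm
#'   (default 25).
#' @param juvenile_size_var variance of juvenile size, mm^2 (default 2).
#' @param maturity_threshold size at which females are treated as
#'   reproductive, mm (default 36, inclusive).
#' @param female_fraction fraction of eggs producing daughters (default 0.5,
#'   an even sex ratio).
#' @param maternal_link_slope optional slope linking maternal size to the
#'   offspring mean size (default 0 = no link; 0.5 is the sensitivity value).
#' @return A list of class `fixed_demography`.
#' @export
fixed_demography <- function(hatch_prob = 0.9, recruit_prob = 0.574,
                             juvenile_size_mean = 25, juvenile_size_var = 2,
                             maturity_threshold = 36, female_fraction = 0.5,
                             maternal_link_slope = 0) {
  stopifnot(hatch_prob >= 0, hatch_prob <= 1,
            recruit_prob >= 0, recruit_prob <= 1,
            female_fraction >= 0, female_fraction <= 1,
            juvenile_size_var > 0, juvenile_size_mean > 0,
            maturity_threshold >= 0)
  structure(list(hatch_prob = hatch_prob, recruit_prob = recruit_prob,
                 juvenile_size_mean = juvenile_size_mean,
                 juvenile_size_var = juvenile_size_var,
                 maturity_threshold = maturity_threshold,
                 female_fraction = female_fraction,
                 maternal_link_slope = maternal_link_slope),
            class = "fixed_demography")
}

#' Published posterior summaries for the red-backed salamander study
#'
#' Posterior means, standard deviations and 95% credible limits of the 30
#' regression coefficients of the joint demographic model, as estimated for
#' the Richmond (VA) cover-board population of *Plethodon cinereus*. Shipped
#' as a packaged reference so the projection and elasticity stages can be run
#' without refitting.
#'
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
redback_estimates <- function() {
  path <- system.file("extdata", "redback_estimates.csv", package = "sizedemog")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Posterior-mean parameter set of the reference study
#'
#' Convenience constructor: the posterior means of [redback_estimates()] as a
#' [vital_rate_params] object. The egg-count residual variance is not part of
#' the published summary table; `egg_var` supplies it (default 4 eggs^2,
#' i.e. a residual SD of 2 eggs, consistent with the raw egg-count spread in
#' the study population).
#'
#' @param egg_var egg-count residual variance (eggs^2).
#' @return A `vital_rate_params` object.
#' @export
posterior_mean_params <- function(egg_var = 4) {
  est <- redback_estimates()
  as_vital_rate_params(c(stats::setNames(est$mean, est$parameter),
                         egg_var = egg_var))
}
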