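#' Expected size after one year of von Bertalanffy growth
#'
#' Growth increment form of the von Bertalanffy model: given size `x` at the
#' start of a year, the expected size one year later is
#' `exp(-K) * x + L * (1 - exp(-K))`. The map is a contraction toward the
#' asymptotic size `L`, which is its fixed point.
#'
#' @param x current snout-to-vent length, mm (non-negative).
#' @param K individual growth rate, 1/yr (positive).
#' @param L asymptotic snout-to-vent length, mm (positive).
#' @return Expected size after one year, mm.
#' @examples
#' growth_mean(25, K = 0.473, L = 43.461)  # ~31.96 mm
#' @export
growth_mean <- function(x, K, L) {
  check_size(x)
  stopifnot(is.finite(K), K > 0, is.finite(L), L > 0)
  exp(-K) * x + L * (1 - exp(-K))
}

#' Residual variance of annual growth
#'
#' The spread of realised size around the von Bertalanffy expectation is
#' modelled as a linear function of current size, `gv_int + gv_slp * x`.
#' Because the fitted line crosses zero at large sizes, the variance is
#' floored at `floor` (default 0.1 mm^2) so the Gaussian growth kernel stays
#' proper; the floor only engages well above the asymptotic size, where the
#' stable population carries negligible mass.
#'
#' @param x current size, mm.
#' @param gv_int intercept, mm^2.
#' @param gv_slp slope, mm^2/mm.
#' @param floor lower bound on the returned variance, mm^2 (positive).
#' @return Growth residual variance, mm^2 (strictly positive).
#' @export
growth_variance <- function(x, gv_int, gv_slp, floor = 0.1) {
  check_size(x)
  stopifnot(is.finite(gv_int), is.finite(gv_slp), floor > 0)
  pmax(gv_int + gv_slp * x, floor)
}

#' Monthly survival probability from the log-log hazard link
#'
#' The log monthly mortality hazard is linear in size,
#' `log(hazard) = haz_int + haz_slp * x`, and monthly survival is
#' `exp(-hazard)`. With a negative slope, survival increases with size.
#'
#' @param x size, mm.
#' @param haz_int hazard intercept (log scale).
#' @param haz_slp hazard size slope, 1/mm.
#' @return Monthly survival probability in (0, 1).
#' @examples
#' monthly_survival(25, -0.817, -0.048)  # ~0.88
#' monthly_survival(45, -0.817, -0.048)  # ~0.95
#' @export
monthly_survival <- function(x, haz_int, haz_slp) {
  check_size(x)
  stopifnot(is.finite(haz_int), is.finite(haz_slp))
  exp(-exp(haz_int + haz_slp * x))
}

#' Survival over an interval on the half-month grid
#'
#' Survey occasions are separated by unequal intervals; survival over an
#' interval of `dt_months` months is the monthly survival raised to
#' `dt_months`. Intervals are only meaningful on the half-month precision of
#' the survey design, so `dt_months` must be a positive multiple of 0.5
#' (12 gives the annual survival used by the projection model).
#'
#' @inheritParams monthly_survival
#' @param dt_months interval length in months; positive multiple of 0.5.
#' @return Survival probability over the interval.
#' @export
interval_survival <- function(x, haz_int, haz_slp, dt_months) {
  stopifnot(is.numeric(dt_months), all(is.finite(dt_months)), all(dt_months > 0))
  if (any(abs(dt_months / 0.5 - round(dt_months / 0.5)) > 1e-8)) {
    stop("interval length must be a multiple of 0.5 months")
  }
  monthly_survival(x, haz_int, haz_slp)^dt_months
}

#' Recapture probability from the logit link
#'
#' Probability that a marked individual alive at a survey occasion is
#' detected, `plogis(rec_int + rec_slp * x)`; larger animals are easier to
#' find under cover boards, so the slope is typically positive.
#'
#' @param x size, mm.
#' @param rec_int logit intercept.
#' @param rec_slp logit size slope, 1/mm.
#' @return Detection probability in (0, 1).
#' @examples
#' recapture_prob(25, -2.120, 0.031)  # ~0.21
#' @export
recapture_prob <- function(x, rec_int, rec_slp) {
  check_size(x)
  stopifnot(is.finite(rec_int), is.finite(rec_slp))
  stats::plogis(rec_int + rec_slp * x)
}

#' Expected egg count of a reproducing female
#'
#' Linear size-fecundity model `egg_int + egg_slp * x`. For kernel assembly
#' the expectation is clamped at zero from below (the line is negative for
#' very small sizes, which never reproduce anyway).
#'
#' @param x female size, mm.
#' @param egg_int intercept, eggs.
#' @param egg_slp slope, eggs/mm.
#' @param clamp if `TRUE` (default) negative expectations are set to 0.
#' @return Expected number of eggs (real-valued).
#' @examples
#' expected_eggs(43, -3.157, 0.250)  # ~7.6 eggs
#' @export
expected_eggs <- function(x, egg_int, egg_slp, clamp = TRUE) {
  check_size(x)
  stopifnot(is.finite(egg_int), is.finite(egg_slp))
  e <- egg_int + egg_slp * x
  if (clamp) pmax(e, 0) else e
}

#' Reproduction indicator
#'
#' Deterministic maturity rule: a female reproduces if and only if her size
#' is at or above the maturity threshold (36 mm by default; the boundary is
#' inclusive).
#'
#' @param x size, mm.
#' @param maturity_threshold threshold size, mm.
#' @return 0/1 vector.
#' @export
reproduction_indicator <- function(x, maturity_threshold = 36) {
  check_size(x)
  as.numeric(x >= maturity_threshold)
}

check_size <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("size must be finite and non-negative")
  }
  invisible(x)
}
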