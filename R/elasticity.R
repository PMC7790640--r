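#' Perturb one growth or survival parameter
#'
#' Returns a copy of the parameter set with a single parameter multiplied by
#' `1 + direction/100`: the von Bertalanffy growth rate `K`, the asymptotic
#' size `L`, or the size slope of the mortality hazard `haz_slp`. The
#' parameter's site/season offsets are scaled by the same factor so the
#' *effective* value changes by exactly `direction` percent at every site
#' and in every season. For the hazard slope (a negative quantity) a
#' "decrease" shrinks its magnitude (`haz_slp * 0.99`), weakening the
#' survival advantage of large animals; set `perturb_sign = "raw"` to
#' instead move the raw coefficient down.
#'
#' @param params a [vital_rate_params] object.
#' @param which one of `"K"`, `"L"`, `"haz_slp"`.
#' @param direction percent change, e.g. `-1` or `+1` (0 returns the
#'   parameters untouched).
#' @param perturb_sign `"magnitude"` (default) or `"raw"`; only affects
#'   `haz_slp`.
#' @return A perturbed `vital_rate_params` object.
#' @export
perturb_vital_rates <- function(params, which = c("K", "L", "haz_slp"),
                                direction = -1,
                                perturb_sign = c("magnitude", "raw")) {
  which <- match.arg(which)
  perturb_sign <- match.arg(perturb_sign)
  p <- as_vital_rate_params(params)
  fac <- 1 + direction / 100
  if (which == "haz_slp" && perturb_sign == "raw" && p[["haz_slp"]] < 0) {
    fac <- 1 - direction / 100
  }
  targets <- switch(which,
    K = c("K", "site2_K", "site3_K"),
    L = c("L", "site2_L", "site3_L"),
    haz_slp = c("haz_slp", "season2_haz_slp"))
  for (t in targets) p[[t]] <- p[[t]] * fac
  validate_vital_rate_params(p)
}

#' Elasticity of lambda to a 1% parameter perturbation
#'
#' Manual perturbation elasticity: rebuilds the kernel with one parameter
#' changed by `direction` percent and reports the relative change
#' `100 * (lambda_p - lambda_0) / lambda_0`, together with the analogous
#' proportional changes (in percent) of the mean and variance of the stable
#' size distribution.
#'
#' @inheritParams perturb_vital_rates
#' @param fixed,mesh,season,site,survival_size passed to [build_kernel()].
#' @return List of class `elasticity`: `E_lambda`, `d_mean_pct`,
#'   `d_var_pct`, `lambda0`, `lambda_p`, `which`, `direction`, `season`.
#' @export
elasticity <- function(params, which = c("K", "L", "haz_slp"), direction = -1,
                       fixed = fixed_demography(), mesh = ipm_mesh(),
                       season = 1, site = 1, survival_size = "post-growth",
                       perturb_sign = "magnitude") {
  which <- match.arg(which)
  base <- lambda_and_stable(build_kernel(params, fixed, mesh, season = season,
                                         site = site, survival_size = survival_size),
                            check = FALSE,
                            maturity_threshold = fixed$maturity_threshold)
  if (base$lambda <= 0) stop("unperturbed lambda must be positive")
  pp <- perturb_vital_rates(params, which, direction, perturb_sign)
  pert <- lambda_and_stable(build_kernel(pp, fixed, mesh, season = season,
                                         site = site, survival_size = survival_size),
                            check = FALSE,
                            maturity_threshold = fixed$maturity_threshold)
  structure(list(
    E_lambda = 100 * (pert$lambda - base$lambda) / base$lambda,
    d_mean_pct = 100 * (pert$mean_size - base$mean_size) / base$mean_size,
    d_var_pct = 100 * (pert$var_size - base$var_size) / base$var_size,
    lambda0 = base$lambda, lambda_p = pert$lambda,
    which = which, direction = direction, season = season),
    class = "elasticity")
}

#' @export
print.elasticity <- function(x, ...) {
  cat(sprintf("E_lambda(%s, %+g%%, season %d) = %.3f%%  (lambda %.4f -> %.4f)\n",
              x$which, x$direction, x$season, x$E_lambda, x$lambda0, x$lambda_p))
  invisible(x)
}

#' Season-averaged elasticity at a parameter point
#'
#' Arithmetic mean of the two seasons' elasticities of lambda, the summary
#' used when a single sensitivity number per parameter is wanted.
#'
#' @inheritParams elasticity
#' @return Numeric: season-averaged `E_lambda` in percent.
#' @export
elasticity_season_avg <- function(params, which, direction = -1,
                                  fixed = fixed_demography(),
                                  mesh = ipm_mesh(), site = 1,
                                  survival_size = "post-growth") {
  mean(vapply(1:2, function(s)
    elasticity(params, which, direction, fixed, mesh, season = s, site = site,
               survival_size = survival_size)$E_lambda, numeric(1)))
}

#' Posterior distribution of elasticities
#'
#' Per-draw perturbation elasticities for violin-style uncertainty
#' reporting; failures of individual draws are counted, not fatal.
#'
#' @param draws a `posterior_draws` object or draws matrix (at least 100
#'   rows).
#' @inheritParams elasticity
#' @return List of class `elasticity_posterior`: `table` (draw, season,
#'   parameter, direction, E_lambda, d_mean_pct, d_var_pct), `summary`
#'   (mean and central 95% quantiles), `n_failed`.
#' @export
posterior_elasticity <- function(draws, which = c("K", "L", "haz_slp"),
                                 direction = -1, fixed = fixed_demography(),
                                 mesh = ipm_mesh(), season = 1, site = 1,
                                 survival_size = "post-growth") {
  which <- match.arg(which)
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  if (nrow(m) < 100) stop("need at least 100 posterior draws")
  rows <- vector("list", nrow(m))
  n_failed <- 0L
  for (i in seq_len(nrow(m))) {
    rows[[i]] <- tryCatch({
      e <- elasticity(m[i, ], which, direction, fixed, mesh, season = season,
                      site = site, survival_size = survival_size)
      data.frame(draw = i, season = season, parameter = which,
                 direction = direction, E_lambda = e$E_lambda,
                 d_mean_pct = e$d_mean_pct, d_var_pct = e$d_var_pct)
    }, error = function(err) { n_failed <<- n_failed + 1L; NULL })
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 summary = c(mean = mean(tab$E_lambda),
                             stats::quantile(tab$E_lambda, c(0.025, 0.5, 0.975))),
                 n_failed = n_failed),
            class = "elasticity_posterior")
}
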