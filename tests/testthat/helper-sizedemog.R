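# shared fixtures, built in code

ref_params <- function() posterior_mean_params()

# small two-season single-site design for fast simulation tests
tiny_design <- function(n = 80, staggered_frac = 0) {
  occ <- data.frame(site = 1, occasion = 1:6,
                    month_offset = c(0, 1, 2, 12, 13, 14),
                    season = rep(1:2, each = 3))
  survey_design(occ, n_initial = n, staggered_frac = staggered_frac)
}

# single-season two-occasion design (one 1-month interval)
one_interval_design <- function(n) {
  occ <- data.frame(site = 1, occasion = 1:2, month_offset = c(0, 1), season = 1)
  survey_design(occ, n_initial = n, staggered_frac = 0)
}

# parameter set with chosen effective rates and no site/season structure
flat_params <- function(monthly_surv = 0.9, p_detect = 0.99,
                        K = 0.473, L = 43.461) {
  vital_rate_params(
    K = K, L = L, gv_int = 2.936, gv_slp = -0.052,
    egg_int = -3.157, egg_slp = 0.25,
    haz_int = log(-log(monthly_surv)), haz_slp = 0,
    rec_int = stats::qlogis(p_detect), rec_slp = 0)
}
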