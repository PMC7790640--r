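# sizedemog

Size-structured demographic analysis of a terrestrial salamander
(*Plethodon cinereus*, the eastern red-backed salamander) from
capture–mark–recapture data. The package provides, as one tested pipeline:

1. **Joint Bayesian estimation** of all size-dependent vital rates from a
   single capture-history table: a Cormack–Jolly–Seber (CJS) model for
   apparent survival and recapture, von Bertalanffy growth in increment
   (Fabens) form with latent-size imputation for animals missed in the
   second field season, and a normal model for egg counts — sampled jointly
   by an adaptive Metropolis sampler written in C++.
2. An **integral projection model (IPM)**: the annual dynamics of the
   snout-to-vent length (SVL) distribution, discretized on a 100-cell mesh
   over 0–65 mm, with asymptotic growth rate λ and stable size
   distribution obtained by power iteration (cross-checked against a dense
   eigensolver).
3. **Manual perturbation elasticities** of λ to ±1% changes in the growth
   rate *K*, the asymptotic size *L*, and the size slope of the mortality
   hazard, optionally propagated over the full posterior.
4. An **individual-based simulator** of the cover-board survey design
   (2 field seasons × 3 sites, 6–8 occasions per season on a half-month
   grid, ~1,000 animals) used for parameter-recovery testing.

## Model

Monthly apparent survival uses a log-log link on a size-dependent mortality
hazard, recapture a logit link, and fecundity a linear size effect:

```
log(hazard)      = e + f·x          S_monthly = exp(-hazard)
logit(p_recap)   = g + h·x
E[eggs]          = c + d·x          eggs ~ Normal(E[eggs], σ²)
x_{t+1}          = exp(-K)·x_t + L·(1 - exp(-K))   (von Bertalanffy, 1-yr step)
Var[x_{t+1}|x_t] = a + b·x_t  (floored at 0.1 mm²)
```

Survival between capture occasions is `S_monthly^Δt` with Δt on a 0.5-month
grid; annual survival in the IPM is `S_monthly^12`. The annual prebreeding
kernel is `A = P + F`, where `P` combines the Gaussian growth kernel with
annual survival and `F` sends egg production of mature females (≥36 mm SVL)
through fixed hatching (0.9) and recruitment (0.574) probabilities and an
even sex ratio into a Normal(25 mm, 2 mm²) recruit-size distribution.
Elasticity is `E_λ = 100·(λ_p − λ_0)/λ_0` for a 1% parameter perturbation.

## Worked example

```r
library(sizedemog)

params <- posterior_mean_params()     # packaged posterior means of the study
r1 <- resolve_vital_rates(params, site = 1, season = 1)

monthly_survival(c(25, 45), r1$haz_int, r1$haz_slp)
#> [1] 0.8754178 0.9503305
recapture_prob(c(25, 45), r1$rec_int, r1$rec_slp)
#> [1] 0.2066890 0.3262929
expected_eggs(c(43, 47), r1$egg_int, r1$egg_slp)
#> [1] 7.593 8.593

k1 <- build_kernel(params, season = 1)
lambda_and_stable(k1)$lambda
#> [1] 0.782873
elasticity(params, "haz_slp", direction = -1, season = 2)$E_lambda
#> [1] -2.786968
```

A 25-mm juvenile survives a month with probability 0.875 and is recaptured
with probability 0.21; a 45-mm adult survives at 0.95 and is recaptured at
0.33. Under season-1 rates the population declines (λ ≈ 0.78 < 1), and a 1%
weakening of the size–survival slope under season-2 rates lowers λ by a
further 2.8%.

End-to-end runs (simulate → fit → project → perturb, with all tables and a
results JSON written next to a resolved config) go through `run_pipeline()`;
see `?run_pipeline` and the methods vignette
(`vignettes/size-structured-demography.Rmd`).

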