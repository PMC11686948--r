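# metapopclim

Climate-driven Bayesian state-space metapopulation models for colonial
seabirds.

Long-lived colonial seabirds such as the Northern gannet are censused as
Apparently Occupied Sites (AOS ≈ breeding pairs), intermittently, over very
long spans. `metapopclim` is for ecologists who want to fit a *mechanistic*
population model to such census series together with nest-monitoring
records and climate covariates, ask which covariates drive fecundity and
recruitment, and project colony trajectories under contrasting emission
scenarios — including the regime shifts that occur when a warming ocean
pulls a colony's marine carrying capacity below its terrestrial one.

## The model

Latent colony sizes $P_{n,t}$ evolve through survival, fecundity,
stage-structured pre-breeder maturation, conspecific-attraction movement
and density-dependent recruitment. Climate enters two demographic rates on
the logit scale (covariates $X_i$ are z-scored; $r \le 2$):

- fecundity: $\operatorname{logit} b_{n,t} = \alpha_0 + \sum_i \sum_r
  \alpha_{ir} X^r_{n,t,i} + \varepsilon_t$, with quadratic terms
  constrained to downward parabolas (an interior climatic optimum);
- marine density dependence: $\operatorname{logit} \eta_{n,t} = \beta_0 +
  \sum_i \sum_r \beta_{ir} X^r_{n,t,i}$;
- terrestrial density dependence: $\nu_n = (\alpha -
  \operatorname{logit} r_e)/K_n$ from an expert-elicited habitat capacity
  $K_n$;
- recruitment: $r_{n,t} = \operatorname{logit}^{-1}(\alpha -
  \max(\nu_n, \eta_{n,t}) P_{n,t})$ with steepness $\alpha = 100$, so the
  stronger regulation channel binds and recruitment falls to the baseline
  rate $r_e$ exactly at the binding capacity
  $\min(K_n, C_{n,t})$, where $C_{n,t} = (\alpha -
  \operatorname{logit} r_e)/\eta_{n,t}$ is the climate-dependent marine
  capacity.

Censuses are log-normal around $P_{n,t}$; monitoring records are binomial
in $b_{n,t}$. A one-year avian-influenza shock reduces adult survival to
0.455 at affected colonies in 2022. Fitting is by an adaptive
Metropolis-within-Gibbs sampler written for this model (compiled core),
model choice by DIC over a 47-structure candidate suite, and forecasting by
propagating posterior draws under two climate scenarios with paired noise.
The methods vignette (`vignettes/climate-metapopulation-models.Rmd`)
documents every equation, prior, sampler move and design decision.

## Worked example

Every stage runs on a self-contained synthetic study, so the pipeline is
fully reproducible from one seed:

```r
library(metapopclim)

study <- simulate_study(n_colonies = 6, years = 1957:2016, seed = 1)
study
#> <synthetic_study> 6 colonies, 60 years ( 1957 - 2016 ), seed 1
#>   true structure: m3.3^251
#>   census points: 142 | fecundity records: 141

fit <- run_mcmc(study, study$spec_true, chains = 2, iter = 4000,
                burn = 1000, thin = 10, seed = 1)
tidy(fit)
#> # A tibble: 8 × 5
#>   term        estimate conf.low conf.high  rhat
#> 1 alpha0         1.02    0.910      1.13  0.999
#> 2 alpha_nsAT     1.61    1.51       1.70  0.999
#> 3 alpha_nsAT2    0.884   0.827      0.939 0.998
#> 4 alpha_prec     0.151   0.0654     0.228 1.00
#> 5 beta0         -6.49   -6.99      -6.24  0.998
#> 6 beta_SST       0.803   0.618      1.15  0.998
#> 7 sigma_b        0.349   0.279      0.431 0.999
#> 8 sigma_obs      0.108   0.0953     0.122 0.999
```

The generating values (fecundity parabola in near-surface air temperature
with linear 1.546 and quadratic magnitude 0.848, precipitation effect
0.139, SST recruitment coefficient 0.881) all sit inside their 95%
credible intervals. `glance(fit)` adds the DIC decomposition and the
Gelman–Rubin convergence flag:

```r
glance(fit)
#> # A tibble: 1 × 8
#>   model      dic  dbar   p_d n_chains n_draws max_rhat converged
#> 1 m3.3^251  608.  552.  55.7        2     600     1.09 TRUE
```

Forecasting under the two scenarios, with the per cent difference in median
2100 colony size (negative = smaller under the high-emission pathway):

```r
fc <- forecast_scenarios(fit, n_draws = 100, seed = 1)
sensitivity(fc, years = 2100)
#> # A tibble: 6 × 3
#>   colony_id  year sensitivity
#> 1 C01        2100    -49.4
#> 2 C02        2100    -49.9
#> 3 C03        2100      0.128
#> 4 C04        2100      0.144
#> 5 C05        2100      0.103
#> 6 C06        2100      0.0722

classify_trajectory(fc)
#> # A tibble: 6 × 2
#>   colony_id pattern
#> 1 C01       diverge_decline
#> 2 C02       diverge_decline
#> 3 C03       plateau_same
#> ...
```

The two southern (warm) colonies, which sit beyond the fecundity optimum
and under marine regulation, are forecast roughly 50% smaller under the
high-emission scenario; the northern colonies are insensitive or benefit
slightly — the spatial mosaic of climate sensitivity the model is designed
to expose. `plot_forecast(fc)`, `plot_dominance(fc)` and
`plot_response_curve(fit, "nsAT")` draw the corresponding figures, and
`run_pipeline()` exposes the same stages as file-based commands
(`simulate`, `fit`, `select`, `forecast`, `sensitivity`; see
`inst/scripts/metapopclim.R`).

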