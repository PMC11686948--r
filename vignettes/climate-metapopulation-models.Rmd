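---
title: "Climate-driven state-space metapopulation models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-driven state-space metapopulation models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`metapopclim` fits a mechanistic Bayesian state-space model of colony
dynamics for long-lived colonial seabirds whose fecundity and recruitment
respond to climate. The observed data are (i) intermittent colony censuses
of Apparently Occupied Sites (AOS, roughly breeding pairs) and (ii) nest
monitoring records (nests checked, chicks seen). The latent process tracks
breeders $P_{n,t}$ and pre-breeders per age class for every colony $n$ and
year $t$.

**Fecundity** is a logit-linear (optionally quadratic) function of
standardized climate covariates with a shared annual disturbance:

$$\operatorname{logit} b_{n,t} = \alpha_0 + \sum_i \sum_{r \le 2}
\alpha_{ir} X_{n,t,i}^r + \varepsilon_t, \qquad
\varepsilon_t \sim \mathcal N(0, \sigma_b^2).$$

Quadratic coefficients are stored as positive magnitudes and applied with a
negative sign, so every fitted quadratic is a downward parabola with an
interior optimum at $x^\ast = \alpha_{i1} / (2\alpha_{i2})$.

**Density-dependent recruitment.** Two competing regulation channels set the
recruitment rate. The terrestrial channel is fixed by a colony's breeding
habitat: $\nu_n = (\alpha - \operatorname{logit} r_e)/K_n$, where $K_n$ is
the terrestrial carrying capacity and $r_e$ the baseline recruitment rate at
capacity. The marine channel varies with climate,
$\operatorname{logit}\eta_{n,t} = \beta_0 + \sum_i\sum_r \beta_{ir}
X_{n,t,i}^r$, and implies a marine carrying capacity
$C_{n,t} = (\alpha - \operatorname{logit} r_e)/\eta_{n,t}$. The stronger
(larger) coefficient binds:

$$r_{n,t} = \operatorname{logit}^{-1}\!\big(\alpha -
\max(\nu_n, \eta_{n,t})\, P_{n,t}\big),$$

with the steepness constant $\alpha = 100$, so recruitment is practically 1
in an empty colony and falls to exactly $r_e$ when the colony reaches the
binding capacity. The signed difference $C_{n,t} - K_n$ ("capacity
dominance") labels a colony terrestrially regulated when positive (ties
included) and marine-regulated when negative.

**Observation model.** Census counts are log-normal around the latent size,
$\log y_{n,t} \sim \mathcal N(\log P_{n,t}, \sigma_{\mathrm{obs}}^2)$ (zero
counts enter as $\log 0.5$); monitoring records are binomial,
$\text{chicks} \sim \mathrm{Binomial}(\text{nests}, b_{n,t})$.

## The reconstructed process step

The annual transition is:

1. adults survive with probability $\phi_{\mathrm{ad}}$ (default 0.94, the
   upper bound for the study species); in the epizootic year (2022) adult
   survival drops to 0.455 at known affected colonies, stays at
   $\phi_{\mathrm{ad}}$ at unaffected ones, and is Uniform(0.455, 0.94) for
   colonies of unknown status (a free parameter in inference, a draw in
   forward simulation);
2. each pair fledges $b_{n,t}$ chicks, converted to pair-equivalents with
   the factor `chick_pair` (default 0.5: two fledglings form one prospective
   AOS);
3. pre-breeder cohorts age with annual survival $\phi_{\mathrm{juv}}$
   (default 0.8) until the age of first breeding `a_first` (default 5,
   matching the species' delayed maturity);
4. the recruitment-eligible pool is redistributed across colonies by
   conspecific attraction: destination weight $\propto P_m$, the natal
   colony boosted by the philopatry factor $\rho$ (default 3); expected-value
   flows conserve individuals exactly;
5. arrivals settle against density dependence; failed settlers re-enter the
   oldest pre-breeder class and retry annually until death.

All process flows are deterministic expected values: environmental
stochasticity enters only through $\varepsilon_t$. That choice concentrates
the latent state in a low-dimensional set (initial sizes plus the
$\varepsilon_t$ series), which is what makes full Bayesian fitting fast.

### Implicit within-season settlement

With $\alpha = 100$ the recruitment logistic is nearly a step function in
$P$, and a naive explicit update $P_{t+1} = \phi P_t + r(P_t) A_t$
overcompensates: the linearized annual map has derivative
$\phi - A\,\mathrm{d}r/\mathrm{d}P \approx -2.5$ at the balance point, so
the deterministic skeleton oscillates around capacity instead of settling.
We therefore treat settlement as a within-season process: arrivals settle
until density dependence — evaluated at the *post-settlement* colony size —
chokes recruitment off,

$$P_{t+1} = \phi P_t + A_t\, r(P_{t+1}),$$

solved per colony-year by a safeguarded Newton iteration (the map is
monotone, so the root is unique). Ecologically this says prospectors compete
with incumbents *and with each other* for sites; numerically it is a
backward-Euler step, unconditionally stable, so deterministic simulations
converge monotonically to a stationary size for any parameter values. The
stationary size sits slightly beyond the $r_e$-defined capacity — by a few
logit-widths of the settlement curve, i.e. a fraction of order $4/\alpha$ —
because the retry pool depresses the equilibrium settlement probability
below $r_e$; this is the "recruitment tail" the tests allow for.

# Priors

* unconstrained linear coefficients: $\mathcal N(0, 1)$;
* parabola coefficients (linear and quadratic part of an order-2 covariate):
  Gamma(1, 1) on the magnitude, i.e. Exponential(1), imposing the sign
  (positive linear, negative quadratic);
* intercepts: $\mathcal N(0, 5)$ — wide, since fitted intercepts in this
  model class span several logits;
* noise SDs $\sigma_b, \sigma_{\mathrm{obs}}$: half-normal(1);
* carrying capacities: log-normal centred on the expert-elicited point value
  with 20% CV — the elicitation gives a point estimate and no distribution,
  and a 20% CV keeps the prior informative without pinning the posterior;
* initial colony sizes: log-normal centred on the earliest census (or
  $K/10$ where a colony was never counted), log-SD 1;
* epizootic-year survival of unknown-status colonies: Uniform(0.455, 0.94).

# Fitting

The sampler is an adaptive random-walk Metropolis-within-Gibbs over the
sampling-scale parameter vector (positive parameters on the log scale,
interval-bounded ones on the logit scale, Jacobians folded into the prior).
Because the trajectory is deterministic given (parameters, $\varepsilon$
series, initial sizes), each scalar update re-simulates only what it
touches: an $\varepsilon_t$ update re-simulates from year $t$ using cached
age-structure checkpoints, and a noise-SD update touches no trajectory at
all. Proposal scales adapt in batches of 50 towards 0.44 acceptance with
diminishing adaptation.

Plain scalar updates mix poorly across three stiff ridges of this posterior,
so the engine adds dedicated moves, all standard Metropolis proposals:

* a *ridge move* trading the fecundity intercept against the whole
  $\varepsilon$ series (the likelihood is exactly invariant; only priors
  vote);
* *compensated coefficient moves*: shift one fecundity coefficient and
  counter-shift each year's $\varepsilon_t$ by the colony-mean predictor
  change, so the likelihood responds only to the identified cross-colony
  contrast;
* *adaptive-covariance block moves* (Haario-style, scaled $2.38/\sqrt d$,
  tuned towards 0.25 acceptance) over the fecundity and recruitment
  coefficient blocks;
* *decoupling directions* for a single linear recruitment covariate: move
  $\operatorname{logit}\eta$ at the 10th-percentile covariate value while
  holding it fixed at the 90th percentile and vice versa, giving the two
  nearly independent data constraints their own axes.

Initial values are data-driven where data allow: the fecundity coefficients
start at a binomial GLM fit to the monitoring records, initial sizes at the
earliest census, capacities at their expert values; chains are jittered.
Convergence is declared when every parameter's Gelman–Rubin statistic is
below 1.1 (the conventional threshold); non-convergence is flagged, never
fatal, and excluded from model selection. The full-scale chain settings
(4 chains × 100,000 iterations, 15,000 burn-in, thinned to every 200th
draw) suit overnight runs; all package tests use desk-scale settings
(4 × 5,000 or smaller), which the recovery study below shows are sufficient
for the synthetic study sizes shipped here.

**DIC.** $\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$,
the deviance focus being the observation level conditional on the latent
states (standard practice for hierarchical models; $\bar\theta$ is the
posterior mean of all sampled quantities). $p_D$ can come out negative for
ill-behaved posteriors and is then reported with a warning. The selection
table reports $\Delta\mathrm{DIC} = \mathrm{DIC}_{\text{null}} -
\mathrm{DIC}_{\text{model}}$, so the best-supported model has the *highest*
$\Delta$. The candidate suite enumerates 47 structures: the null, five
single-covariate fecundity models, five single-covariate recruitment models,
all 25 one-covariate-each pairs, three quadratic extensions of the best pair
(nsAT fecundity + SST recruitment), and eight models adding a second
fecundity covariate with nsAT linear or quadratic.

# Covariate extraction

Colony-specific covariate series come from gridded monthly fields through
at-sea density surfaces. The shipped surface builder is a deliberately
simple proxy for a full mechanistic space-use model: an exponential kernel
over sea cells with range $\lambda \propto \sqrt{\text{colony size}}$,
contested cells split between colonies in proportion to each kernel value,
weights normalized to sum to one per colony. Extraction averages February
through September (the colony attendance period) per cell, then takes the
surface-weighted mean. Weights are normalized — a raw weighted *sum* would
scale covariates with colony size, which is incompatible with z-scoring
shared response curves. Surfaces are rebuilt on 20-year epochs (1900, 1920,
…, 2000, 2016); every year from 2016 on, including all forecast years, uses
the 2016 surface. The fitting series for 2015–2016 (beyond the hindcast
horizon) is the mean of the two scenario values. Covariates are z-scored
pooling all colony-years in the fitting window, one mean and SD per
covariate, and the same constants standardize forecast years — forecast
z-scores may therefore leave the fitted range, which is exactly the
extrapolation the scenario contrast is about. Gridded input is accepted as
long-format CSV of cell-month values with cell centroids in decimal
degrees.

# The synthetic-study generator

`simulate_study()` builds a complete study: six colonies spanning 48–70°N
(roughly a 10 °C near-surface air-temperature gradient, so colonies sit on
both sides of the fecundity optimum), terrestrial capacities falling from
60,000 to 2,000 AOS from south to north (southern colonies large enough for
marine regulation to bind), epizootic status mostly "affected" with the
northernmost colony unaffected and one unknown. Climate per covariate is a
latitude-dependent baseline plus a linear trend plus AR(1) noise; the two
scenarios share the hindcast through 2014 and its innovations afterwards,
differing only in trend, with the high-emission pathway warming roughly
five times faster. True coefficients default to the magnitudes of published
posterior medians for this model class (fecundity parabola in nsAT with a
small positive precipitation effect; SST-driven marine density dependence);
$\sigma_b = 0.3$, $\sigma_{\mathrm{obs}} = 0.1$. Censuses are observed at
40% of colony-years in blocks (a two-state Markov chain with mean observed
run of ten years, mimicking intermittent historical censuses); fecundity is
monitored at 40% of colony-years with 40–250 nests. Colonies start at 20%
of capacity, so trajectories traverse growth, approach and regulation —
the phases that identify the recruitment side.

What the generator does *not* emulate: real coastline geometry or CMIP
spatial fields (climate is colony-level, not gridded), demographic
stochasticity (process noise beyond $\varepsilon_t$), observation-effort
heterogeneity, and colonisation of new sites. Passing recovery tests on
these studies therefore demonstrates that the estimation machinery is
consistent under the model's own assumptions — not that the model is
correctly specified for any particular real dataset.

# Forecasting

Each retained posterior draw re-simulates the fitting window (recovering
the terminal age structure exactly, since the process is deterministic
given the draw) and continues through 2100 under each scenario's
covariates. Future $\varepsilon_t$ and the unknown-status epizootic
survival are drawn once per posterior draw and reused across scenarios, so
scenario contrasts reflect climate, not Monte Carlo noise. The
metapopulation total is summarized as the median of per-draw totals (which
respects cross-colony correlation); the sum of per-colony medians is
reported alongside for reference. Colony *sensitivity* is the signed
percent difference in median size, $100(\mathrm{med}_{SSP5} -
\mathrm{med}_{SSP1})/\mathrm{med}_{SSP1}$, undefined (NA) where the
low-emission median is zero. Trajectory patterns are labelled by explicit
rules (thresholds all exposed): scenarios "not differing" means an
end-horizon difference under 10%; "plateaued" means a late-horizon relative
slope under 0.5%/yr over the final 20 years; scenario-driven decline means
the high-emission end median below 90% of its own peak; "drastic decline"
means ending below half the 2030 median under both scenarios.

# Numerical choices

* settlement root: safeguarded Newton, tolerance $10^{-7}(1 + A)$
  individuals, at most 12 iterations, with closed-form shortcuts where the
  logistic saturates ($|\alpha - \mathrm{dd}\cdot P| > 36$);
* cached-state floating-point drift in the sampler is capped by a full
  recomputation every 500 iterations;
* zero censuses enter as $\log 0.5$; fecundities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the binomial likelihood;
* capacity-dominance ties are labelled terrestrial;
* $\varepsilon_t$ is shared across colonies within a year (it carries a
  year subscript only); whether it should be colony-specific is an open
  modelling question we resolve in favour of the more parsimonious reading;
* the baseline equilibrium recruitment rate $r_e$ is not identified by any
  published value; the default 0.3 is exposed in
  `demographic_params()` and must be identical in the terrestrial and
  marine capacity formulas (the constructor enforces a single value).

# Known limitations

Conspecific attraction carries no distance decay, so a large colony attracts
pre-breeders from arbitrarily far away; there is no spatially explicit
founding of new colonies; survival carries no climate signal (breeding
season model); the deterministic-given-$\varepsilon$ process understates
latent-state uncertainty relative to a fully stochastic formulation — the
census noise term absorbs what demographic stochasticity there is. The
desk-scale problem sizes used throughout the tests (six colonies, sixty
years, thousands rather than hundreds of thousands of iterations) are the
package's reference configuration for methodological validation; fitting a
century-scale multi-colony dataset at full chain settings is an overnight
computation.
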