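# Synthetic studies: a colony network on a latitudinal climate gradient,
# scenario-divergent covariate series, latent trajectories from the process
# model, and census/fecundity observations with the assumed error structure.
# Everything is reproducible from a single integer seed.

#' Default synthetic colony network
#'
#' Six colonies spanning 48-70 degrees North, i.e. roughly a 10 degree C
#' gradient in near-surface air temperature, so that colonies sit on both
#' sides of the fecundity optimum. Terrestrial carrying capacities fall from
#' 60,000 AOS in the south to 2,000 AOS in the north (southern colonies
#' large enough for marine regulation to bind). Avian-influenza status
#' mirrors the observed epizootic: most colonies affected, the northernmost
#' unaffected, one unknown.
#'
#' @param n_colonies Number of colonies (default 6).
#' @return Tibble (`colony_id`, `name`, `lon`, `lat`, `K_expert`,
#'   `hpai_status`).
#' @export
generate_colonies <- function(n_colonies = 6) {
  lat <- seq(48, 70, length.out = n_colonies)
  K <- round(exp(seq(log(60000), log(2000), length.out = n_colonies)))
  status <- rep("affected", n_colonies)
  status[n_colonies] <- "unaffected"
  if (n_colonies >= 3) status[n_colonies - 1] <- "unknown"
  tibble::tibble(
    colony_id = sprintf("C%02d", seq_len(n_colonies)),
    name = sprintf("synthetic_colony_%02d", seq_len(n_colonies)),
    lon = seq(-5, 20, length.out = n_colonies),
    lat = lat,
    K_expert = K,
    hpai_status = status
  )
}

# Latitude-dependent climatological baselines (native units) and per-year
# warming trends for the hindcast and the two scenarios.
climate_settings_default <- function() {
  list(
    base = list( # value at 48N, and change per degree latitude northwards
      nsAT = c(int = 14, slope = -0.5),   # degC, Feb-Sep mean
      SST = c(int = 12, slope = -0.35),   # degC
      SLM = c(int = 35.2, slope = -0.05), # PSU
      nsWS = c(int = 7.5, slope = 0.05),  # m/s
      prec = c(int = 70, slope = 1.0)     # mm/month
    ),
    trend = list( # per-year trends: hindcast (from 1900), SSP1/SSP5 (from 2015)
      nsAT = c(hind = 0.008, SSP1 = 0.010, SSP5 = 0.050),
      SST = c(hind = 0.006, SSP1 = 0.007, SSP5 = 0.035),
      SLM = c(hind = -0.0005, SSP1 = -0.001, SSP5 = -0.004),
      nsWS = c(hind = 0, SSP1 = 0, SSP5 = 0.005),
      prec = c(hind = 0.02, SSP1 = 0.02, SSP5 = 0.15)
    ),
    ar = list( # AR(1) interannual noise per covariate: phi, innovation SD
      nsAT = c(phi = 0.5, sd = 0.40),
      SST = c(phi = 0.5, sd = 0.30),
      SLM = c(phi = 0.5, sd = 0.08),
      nsWS = c(phi = 0.3, sd = 0.40),
      prec = c(phi = 0.3, sd = 6.0)
    )
  )
}

#' Generate colony-level scenario climate series
#'
#' Per colony and covariate: a latitude-dependent climatological baseline, a
#' linear warming (or freshening/wetting) trend, and AR(1) interannual
#' noise. The two scenarios share the hindcast exactly through 2014 and its
#' noise innovations afterwards, so they differ only through their trends,
#' with the high-emission pathway moving faster. The fitting series
#' (`scenario = "hindcast"`, through `max(hindcast_years)`) uses the mean of
#' the two scenarios for the years past the hindcast horizon (2015-2016).
#'
#' @param colonies Colony tibble from [generate_colonies()].
#' @param years Full span of years (default 1900:2100).
#' @param hindcast_years Fitting-window years (default 1900:2016).
#' @param settings Baselines/trends/noise, see
#'   `metapopclim:::climate_settings_default()`.
#' @param seed Integer seed (all randomness is drawn from it).
#' @return Long climate tibble (`colony_id`, `scenario`, `year`,
#'   `covariate`, `value`), raw units (not standardized).
#' @export
generate_climate <- function(colonies, years = 1900:2100,
                             hindcast_years = 1900:2016,
                             settings = climate_settings_default(),
                             seed = 1L) {
  stopifnot(min(hindcast_years) >= min(years))
  hind_end <- 2014L # scenarios identical through this year
  withr_seed <- function(code) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  withr_seed({
    out <- purrr::map_dfr(mpc_covariates(), function(cv) {
      b <- settings$base[[cv]]
      tr <- settings$trend[[cv]]
      ar <- settings$ar[[cv]]
      purrr::pmap_dfr(colonies, function(colony_id, lat, ...) {
        n <- length(years)
        innov <- rnorm(n, 0, ar[["sd"]])
        noise <- numeric(n)
        for (t in seq_len(n)) {
          noise[t] <- if (t == 1) innov[1] else ar[["phi"]] * noise[t - 1] + innov[t]
        }
        base_val <- b[["int"]] + b[["slope"]] * (lat - 48)
        t_hind <- pmin(years, hind_end) - min(years)
        trend_hind <- tr[["hind"]] * t_hind
        extra <- function(rate) rate * pmax(0, years - hind_end)
        mk <- function(scen, rate) {
          tibble::tibble(colony_id = colony_id, scenario = scen, year = years,
                         covariate = cv,
                         value = base_val + trend_hind + extra(rate) + noise)
        }
        dplyr::bind_rows(mk("SSP1", tr[["SSP1"]]), mk("SSP5", tr[["SSP5"]]))
      })
    })
    # fitting series: hindcast through 2014 (scenarios agree there), then the
    # scenario mean for the remaining fitting years
    fit <- out |>
      dplyr::filter(.data$year %in% hindcast_years) |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("colony_id", "year", "covariate")) |>
      dplyr::mutate(scenario = "hindcast")
    fc <- dplyr::filter(out, .data$year > max(hindcast_years))
    dplyr::bind_rows(fit, fc) |>
      dplyr::select("colony_id", "scenario", "year", "covariate", "value") |>
      dplyr::arrange(.data$scenario, .data$covariate, .data$colony_id, .data$year)
  })
}

#' Simulate census and fecundity observations from a latent trajectory
#'
#' Census: `log(count) ~ Normal(log P, sigma_obs)`, rounded to integer AOS,
#' at colony-years selected by a blocky missingness process (a two-state
#' Markov chain, emulating intermittent historical censuses). Fecundity:
#' `chicks ~ Binomial(nests, b)` at a sparse random subset of colony-years.
#'
#' @param latent Tidy latent trajectory with columns `colony_id`, `year`,
#'   `P` and `b` (fecundity actually realised that year; rows with `NA` `b`
#'   are never sampled for fecundity).
#' @param params A [demographic_params()] (uses `sigma_obs`).
#' @param census_obs_rate Long-run fraction of colony-years with a census
#'   (default 0.4, i.e. 60 percent missing).
#' @param census_run_length Mean length (years) of an observed block.
#' @param fecundity_obs_rate Fraction of colony-years with fecundity
#'   monitoring (default 0.4, matching sparse long-term monitoring schemes).
#' @param nests_range Range of monitored nests per colony-year.
#' @param seed Integer seed.
#' @return List of tibbles: `census` (`colony_id`, `year`, `aos_count`) and
#'   `fecundity` (`colony_id`, `year`, `nests`, `chicks`).
#' @export
simulate_observations <- function(latent, params,
                                  census_obs_rate = 0.4,
                                  census_run_length = 10,
                                  fecundity_obs_rate = 0.4,
                                  nests_range = c(40, 250),
                                  seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  latent <- dplyr::arrange(tibble::as_tibble(latent), .data$colony_id, .data$year)

  # two-state (observed / unobserved) Markov chain with the requested
  # stationary observation rate and mean observed-run length
  p_leave_obs <- 1 / census_run_length
  p_enter_obs <- p_leave_obs * census_obs_rate / (1 - census_obs_rate)
  census <- latent |>
    dplyr::group_by(.data$colony_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      obs <- logical(n)
      obs[1] <- runif(1) < census_obs_rate
      for (t in seq_len(n)[-1]) {
        p <- if (obs[t - 1]) 1 - p_leave_obs else p_enter_obs
        obs[t] <- runif(1) < p
      }
      df[obs, c("year", "P")]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(aos_count = pmax(0L, as.integer(round(
      exp(rnorm(dplyr::n(), log(pmax(.data$P, 1e-12)), params$sigma_obs))
    )))) |>
    dplyr::select("colony_id", "year", "aos_count")

  fec_pool <- dplyr::filter(latent, !is.na(.data$b))
  take <- runif(nrow(fec_pool)) < fecundity_obs_rate
  fecundity <- fec_pool[take, , drop = FALSE] |>
    dplyr::mutate(nests = sample(nests_range[1]:nests_range[2], dplyr::n(),
                                 replace = TRUE),
                  chicks = rbinom(dplyr::n(), .data$nests, .data$b)) |>
    dplyr::select("colony_id", "year", "nests", "chicks")

  list(census = census, fecundity = fecundity)
}

#' Default true parameters of a synthetic study
#'
#' Coefficients follow the magnitude of posterior medians reported for this
#' model class: a fecundity parabola in near-surface air temperature with a
#' small positive precipitation effect, and an SST-driven marine density
#' dependence.
#'
#' @param colonies Colony tibble ( `K_expert` becomes the true `K`).
#' @param ... Overrides passed on to [demographic_params()].
#' @return A [demographic_params()] object.
#' @export
default_true_params <- function(colonies, ...) {
  args <- list(
    alpha0 = 0.969,
    alpha_lin = c(nsAT = 1.546, prec = 0.139),
    alpha_quad = c(nsAT = 0.848),
    beta0 = -6.619,
    beta_lin = c(SST = 0.881),
    sigma_b = 0.3,
    sigma_obs = 0.1,
    K = setNames(colonies$K_expert, colonies$colony_id)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(demographic_params, args)
}

#' Generate a complete synthetic study
#'
#' Builds a colony network, scenario climate (standardized over the fitting
#' window), true parameters and model structure, a latent trajectory
#' simulated from the process model with annual logit-scale fecundity noise,
#' and census/fecundity observations — the full set of inputs the fitting
#' and forecasting stages consume, reproducible from one seed.
#'
#' @param n_colonies Number of colonies.
#' @param years Fitting-window years of the latent trajectory
#'   (default 1957:2016, sixty annual states).
#' @param spec_true True model structure (default: quadratic nsAT + linear
#'   precipitation on fecundity, linear SST on recruitment).
#' @param params_true True parameters; default [default_true_params()].
#' @param init_frac Initial colony size as a fraction of `K` (default 0.2,
#'   colonies recovering towards capacity).
#' @param seed Integer seed controlling climate, process noise and
#'   observations.
#' @param ... Passed to [simulate_observations()].
#' @return An object of class `synthetic_study`: list with `colonies`,
#'   `climate` (standardized; constants attached), `params_true`,
#'   `spec_true`, `latent`, `census`, `fecundity`, `eps_true`, `years`,
#'   `seed`.
#' @export
simulate_study <- function(n_colonies = 6, years = 1957:2016,
                           spec_true = model_spec(fecundity = c(nsAT = 2, prec = 1),
                                                  recruitment = c(SST = 1)),
                           params_true = NULL, init_frac = 0.2,
                           seed = 1L, ...) {
  colonies <- generate_colonies(n_colonies)
  climate_raw <- generate_climate(colonies, years = min(years):2100,
                                  hindcast_years = min(years):max(years),
                                  seed = seed)
  climate <- standardize_climate(climate_raw, window = years)
  if (is.null(params_true)) params_true <- default_true_params(colonies)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 1L)
  n_step <- length(years) - 1L
  eps <- setNames(rnorm(n_step, 0, params_true$sigma_b),
                  as.character(years[-length(years)]))
  P0 <- setNames(init_frac * params_true$K[colonies$colony_id],
                 colonies$colony_id)
  cl_wide <- climate_wide(climate, scenario = "hindcast")
  # pre-breeder pools seeded from year-0 fecundity (climate and noise included)
  cl0 <- cl_wide[cl_wide$year == min(years), , drop = FALSE]
  cl0 <- cl0[match(colonies$colony_id, cl0$colony_id), , drop = FALSE]
  b0 <- fecundity_rate(cl0, params_true, spec_true,
                       eps_t = eps[[as.character(min(years))]])
  state0 <- colony_state(P0, min(years), params_true, b0 = b0)
  latent <- simulate_metapopulation(state0, cl_wide, params_true, spec_true,
                                    n_years = n_step, eps = eps)
  obs <- simulate_observations(latent, params_true, seed = seed + 2L, ...)

  structure(
    list(colonies = colonies, climate = climate, params_true = params_true,
         spec_true = spec_true, latent = latent, census = obs$census,
         fecundity = obs$fecundity, eps_true = eps, years = years,
         seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", nrow(x$colonies), "colonies,",
      length(x$years), "years (", min(x$years), "-", max(x$years), "), seed",
      x$seed, "\n")
  cat("  true structure:", x$spec_true$id, "\n")
  cat("  census points:", nrow(x$census),
      "| fecundity records:", nrow(x$fecundity), "\n")
  invisible(x)
}
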