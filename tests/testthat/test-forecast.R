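# Scenario forecasting, sensitivity and trajectory classification.

small_fit_forecast <- function(seed = 13, ...) {
  study <- simulate_study(n_colonies = 4, years = 1987:2016, seed = seed)
  fit <- suppressWarnings(run_mcmc(fit_data(study), study$spec_true,
                                   chains = 2, iter = 800, burn = 300,
                                   thin = 5, seed = seed))
  list(study = study, fit = fit)
}

test_that("identical scenario climate with paired seeds gives zero sensitivity", {
  sf <- small_fit_forecast()
  climate <- sf$study$climate
  # clone SSP1 into SSP5 so the scenarios are literally identical
  ssp1 <- dplyr::filter(climate, scenario == "SSP1")
  cloned <- dplyr::bind_rows(dplyr::filter(climate, scenario != "SSP5"),
                             dplyr::mutate(ssp1, scenario = "SSP5"))
  fc <- forecast_scenarios(sf$fit, climate = cloned, n_draws = 40, seed = 5)
  sens <- sensitivity(fc)
  expect_true(all(sens$sensitivity == 0))
  # the paired trajectories themselves are identical
  tr <- tidyr::pivot_wider(fc$trajectories[, c("scenario", "colony_id",
                                               "year", "median")],
                           names_from = scenario, values_from = median)
  expect_identical(tr$SSP1, tr$SSP5)
})

test_that("a warmer high-emission future hurts a colony beyond the optimum", {
  sf <- small_fit_forecast(seed = 17)
  climate <- sf$study$climate
  # construct SSP5 = SSP1 plus strong extra warming at the warmest colony
  ssp1 <- dplyr::filter(climate, scenario == "SSP1")
  warm <- dplyr::mutate(
    ssp1, scenario = "SSP5",
    value = value + ifelse(colony_id == "C01" &
                             covariate %in% c("nsAT") & year >= 2017,
                           2.5, 0))
  constructed <- dplyr::bind_rows(dplyr::filter(climate, scenario != "SSP5"),
                                  warm)
  fc <- forecast_scenarios(sf$fit, climate = constructed, n_draws = 40,
                           seed = 5)
  sens <- sensitivity(fc, years = 2100)
  expect_lt(sens$sensitivity[sens$colony_id == "C01"], 0)
})

test_that("sensitivity implements the signed percent difference", {
  fake <- structure(list(
    trajectories = tidyr::crossing(scenario = c("SSP1", "SSP5"),
                                   colony_id = c("A", "B", "C"),
                                   year = 2100) |>
      dplyr::mutate(median = dplyr::case_when(
        colony_id == "A" ~ 1000,
        colony_id == "B" & scenario == "SSP5" ~ 2000,
        colony_id == "B" ~ 1000,
        colony_id == "C" & scenario == "SSP5" ~ 500,
        TRUE ~ 1000)),
    years = 2017:2100), class = "metapop_forecast")
  s <- sensitivity(fake, years = 2100)
  expect_equal(s$sensitivity[s$colony_id == "A"], 0)
  expect_equal(s$sensitivity[s$colony_id == "B"], 100)
  expect_equal(s$sensitivity[s$colony_id == "C"], -50)
  # zero low-emission median: undefined, reported missing
  fake0 <- fake
  fake0$trajectories$median[fake0$trajectories$colony_id == "A"] <- 0
  expect_true(is.na(sensitivity(fake0, years = 2100)$sensitivity[1]))
})

make_forecast_fixture <- function(traj_fun) {
  years <- 2017:2100
  structure(list(
    trajectories = tidyr::crossing(scenario = c("SSP1", "SSP5"),
                                   colony_id = "X", year = years) |>
      dplyr::mutate(median = traj_fun(year, scenario)),
    years = years), class = "metapop_forecast")
}

test_that("trajectory classification reproduces the four patterns", {
  flat <- make_forecast_fixture(function(y, s) rep(1000, length(y)))
  expect_equal(classify_trajectory(flat)$pattern, "plateau_same")

  rising <- make_forecast_fixture(function(y, s) {
    1000 * exp(0.02 * (y - 2017)) * ifelse(s == "SSP5", 1.2, 1)
  })
  expect_equal(classify_trajectory(rising)$pattern, "increase_unbounded")

  diverging <- make_forecast_fixture(function(y, s) {
    ifelse(s == "SSP1", 1000,
           ifelse(y < 2050, 1000, 1000 * exp(-0.02 * (y - 2050))))
  })
  expect_equal(classify_trajectory(diverging)$pattern, "diverge_decline")

  crashing <- make_forecast_fixture(function(y, s) {
    1000 * exp(-0.04 * (y - 2017)) * ifelse(s == "SSP5", 0.8, 1)
  })
  expect_equal(classify_trajectory(crashing)$pattern, "decline_both")
})

test_that("forecast summaries report both totals and are internally consistent", {
  sf <- small_fit_forecast(seed = 19)
  fc <- forecast_scenarios(sf$fit, n_draws = 30, seed = 2)
  expect_setequal(unique(fc$totals$scenario), c("SSP1", "SSP5"))
  # both metapopulation summaries are present and of the same magnitude
  tot <- dplyr::filter(fc$totals, year == 2100, scenario == "SSP1")
  expect_true(tot$sum_of_medians > 0.5 * tot$median &&
                tot$sum_of_medians < 2 * tot$median)
  # dominance switches sign exactly where C crosses K
  tr <- dplyr::filter(fc$trajectories, scenario == "SSP5")
  expect_true(all((tr$regulation == "terrestrial") == (tr$dominance >= 0)))
  # scenarios share the fitted window exactly (paired history)
  hist <- dplyr::filter(fc$trajectories, year <= 2016)
  wide <- tidyr::pivot_wider(hist[, c("scenario", "colony_id", "year", "median")],
                             names_from = scenario, values_from = median)
  expect_equal(wide$SSP1, wide$SSP5, tolerance = 1e-9)
  # epizootic shock: a drop across 2022 in every scenario
  tots_2021 <- dplyr::filter(fc$totals, year == 2021)
  tots_2023 <- dplyr::filter(fc$totals, year == 2023)
  expect_true(all(tots_2023$median < tots_2021$median))
})

test_that("a noise-free single-colony forecast matches manual iteration", {
  # manual five-year iteration of the process equations with an independent
  # root finder for the implicit settlement step
  p <- demographic_params(alpha0 = 1, beta0 = -6, K = c(A = 5000),
                          sigma_b = 0)
  s <- model_spec()
  climate <- tibble::tibble(colony_id = "A", year = 2000:2005, SST = 0,
                            SLM = 0, nsAT = 0, nsWS = 0, prec = 0)
  st <- colony_state(c(A = 3000), 2000L, p)
  got <- simulate_metapopulation(st, climate, p, s, n_years = 5)

  b <- plogis(1)
  eta <- plogis(-6)
  nu <- (100 - qlogis(0.3)) / 5000
  dd <- max(nu, eta)
  P <- 3000
  J <- 0.5 * b * 3000 * 0.8^(0:4)
  for (k in 1:5) {
    eligible <- 0.8 * (J[4] + J[5])
    arrivals <- eligible # single colony: everyone stays natal
    settle <- function(x) x - 0.94 * P - arrivals * plogis(100 - dd * x)
    x <- stats::uniroot(settle, c(0.94 * P, 0.94 * P + arrivals),
                        tol = 1e-10)$root
    J <- c(0.5 * b * P, 0.8 * J[1:3], arrivals - (x - 0.94 * P))
    P <- x
  }
  expect_equal(got$P[got$year == 2005], P, tolerance = 1e-6)
})
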