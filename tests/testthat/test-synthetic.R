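# Synthetic-study generator: climate, observations, reproducibility.

test_that("synthetic studies are byte-identical under one seed", {
  s1 <- tiny_study(seed = 11)
  s2 <- tiny_study(seed = 11)
  expect_identical(s1$census, s2$census)
  expect_identical(s1$fecundity, s2$fecundity)
  expect_identical(s1$latent, s2$latent)
  s3 <- tiny_study(seed = 12)
  expect_false(identical(s1$census, s3$census))
  # different seeds change observations, never the true parameter values
  expect_identical(unclass(s1$params_true), unclass(s3$params_true))
})

test_that("scenario climate shares the hindcast and diverges afterwards", {
  cl <- generate_climate(generate_colonies(3), years = 1990:2060,
                         hindcast_years = 1990:2016, seed = 2)
  wide <- tidyr::pivot_wider(cl, names_from = scenario, values_from = value)
  pre <- dplyr::filter(wide, year <= 2014, !is.na(SSP1))
  expect_equal(pre$SSP1, pre$SSP5, tolerance = 1e-12)
  post <- dplyr::filter(wide, year == 2060, covariate == "nsAT")
  expect_true(all(post$SSP5 > post$SSP1))
  # latitude gradient: the southernmost colony is the warmest
  base <- cl |>
    dplyr::filter(covariate == "nsAT", scenario == "hindcast") |>
    dplyr::summarise(m = mean(value), .by = colony_id)
  expect_equal(base$colony_id[which.max(base$m)], "C01")
})

test_that("interannual noise has the configured AR(1) autocorrelation", {
  colonies <- generate_colonies(1)
  settings <- climate_settings_default <- metapopclim:::climate_settings_default()
  for (cv in mpc_covariates()) {
    settings$trend[[cv]][] <- 0
    settings$base[[cv]]["slope"] <- 0
  }
  settings$ar$SST <- c(phi = 0.5, sd = 1)
  cl <- generate_climate(colonies, years = 1:10000, hindcast_years = 1:10000,
                         settings = settings, seed = 5)
  x <- dplyr::filter(cl, covariate == "SST", scenario == "hindcast") |>
    dplyr::arrange(year) |>
    dplyr::pull(value)
  rho1 <- stats::cor(x[-1], x[-length(x)])
  expect_equal(rho1, 0.5, tolerance = 0.05)
})

test_that("observation simulation matches its sampling model", {
  latent <- tibble::tibble(colony_id = "A", year = 2001:2060,
                           P = 1000, b = 0.5)
  p <- demographic_params(sigma_obs = 0, K = c(A = 1000))
  obs <- simulate_observations(latent, p, census_obs_rate = 1,
                               fecundity_obs_rate = 1, seed = 3)
  # noise-free census equals the rounded latent abundance
  expect_true(all(obs$census$aos_count == 1000))
  expect_true(all(obs$fecundity$chicks <= obs$fecundity$nests))

  # perfect fecundity: every monitored nest holds a chick
  obs1 <- simulate_observations(dplyr::mutate(latent, b = 1), p,
                                census_obs_rate = 1, fecundity_obs_rate = 1,
                                seed = 3)
  expect_true(all(obs1$fecundity$chicks == obs1$fecundity$nests))

  # binomial sampling: the pooled rate concentrates on b
  big <- tibble::tibble(colony_id = "A", year = 1:5000, P = 100, b = 0.5)
  obsb <- simulate_observations(big, p, census_obs_rate = 0.1,
                                fecundity_obs_rate = 1,
                                nests_range = c(200, 200), seed = 9)
  rate <- sum(obsb$fecundity$chicks) / sum(obsb$fecundity$nests)
  se <- sqrt(0.25 / sum(obsb$fecundity$nests))
  expect_lt(abs(rate - 0.5), 3 * se)

  # blocky missingness with the requested long-run observation rate
  obs_frac <- nrow(obsb$census) / nrow(big)
  expect_equal(obs_frac, 0.1, tolerance = 0.05)
})

test_that("the default network spans the fecundity optimum in both directions", {
  study <- simulate_study(seed = 21)
  wide <- climate_wide(study$climate, scenario = "hindcast")
  zbar <- wide |>
    dplyr::filter(year %in% study$years) |>
    dplyr::summarise(nsAT = mean(nsAT), .by = colony_id)
  xstar <- study$params_true$alpha_lin[["nsAT"]] /
    (2 * study$params_true$alpha_quad[["nsAT"]])
  expect_gt(max(zbar$nsAT), xstar) # at least one colony above the optimum
  expect_lt(min(zbar$nsAT), xstar) # and one below
  # both regulation regimes are present at the end of the fitting window
  final <- dplyr::filter(wide, year == max(study$years))
  eta <- marine_dd(final, study$params_true, study$spec_true)
  dom <- capacity_dominance(marine_carrying_capacity(eta, study$params_true),
                            study$params_true$K[final$colony_id])
  expect_setequal(unique(dom$regulation), c("marine", "terrestrial"))
})
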