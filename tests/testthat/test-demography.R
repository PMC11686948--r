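# Closed-form demographic rates and the annual process step.

test_that("fecundity response reproduces the published peak and scalar cases", {
  p <- table_params()
  s <- best_spec()
  xstar <- 1.546 / (2 * 0.848)
  # peak of the nsAT parabola with precipitation at its standardized mean
  expect_equal(round(fecundity_rate(zrow(nsAT = xstar), p, s), 2), 0.84)
  # intercept-only evaluation
  expect_equal(fecundity_rate(zrow(), p, s), plogis(0.969), tolerance = 1e-12)
  # parabola symmetry about the vertex
  for (d in c(0.1, 0.7, 2.3)) {
    expect_equal(fecundity_rate(zrow(nsAT = xstar + d), p, s),
                 fecundity_rate(zrow(nsAT = xstar - d), p, s),
                 tolerance = 1e-12)
  }
  # annual noise shifts the logit directly
  expect_equal(fecundity_rate(zrow(), p, s, eps_t = 0.5),
               plogis(0.969 + 0.5), tolerance = 1e-12)
  expect_error(fecundity_rate(tibble::tibble(SST = 0), p, s), "absent")
})

test_that("marine density dependence is a clean logit-linear response", {
  p <- table_params()
  s <- best_spec()
  expect_equal(marine_dd(zrow(), p, s), plogis(-6.619), tolerance = 1e-12)
  expect_equal(marine_dd(zrow(), p, s), 1.33e-3, tolerance = 1e-2)
  # monotone increasing in SST when the coefficient is positive
  z <- seq(-3, 3, by = 0.5)
  eta <- marine_dd(tibble::tibble(SST = z, SLM = 0, nsAT = 0, nsWS = 0,
                                  prec = 0), p, s)
  expect_true(all(diff(eta) > 0))
  # logit-link limit
  expect_lt(marine_dd(zrow(SST = -40), p, s), 1e-15)
})

test_that("terrestrial density dependence inverts carrying capacity", {
  p <- demographic_params(re = 0.5, K = c(A = 10000))
  expect_equal(terrestrial_dd(10000, p), 0.01, tolerance = 1e-12)
  p2 <- demographic_params(re = 0.3, K = c(A = 1000))
  expect_equal(terrestrial_dd(1000, p2), (100 - log(3 / 7)) / 1000,
               tolerance = 1e-12)
  expect_equal(terrestrial_dd(2000, p2), terrestrial_dd(1000, p2) / 2,
               tolerance = 1e-12)
  expect_error(terrestrial_dd(0, p), "> 0")
})

test_that("recruitment boundary behaviour and capacity identities hold", {
  p <- demographic_params(re = 0.5, K = c(A = 10000))
  expect_equal(recruitment_rate(0, 0.01, 0.001, p), 1, tolerance = 1e-12)
  # eta dominant at P = C gives exactly the baseline rate
  eta <- 1.33e-3
  C <- marine_carrying_capacity(eta, p)
  expect_equal(recruitment_rate(C, 0, eta, p), p$re, tolerance = 1e-9)
  expect_equal(C, 7.5e4, tolerance = 1e-2)
  # hand-derived midpoint case
  expect_equal(recruitment_rate(10000, 0.01, 0.001, p), 0.5, tolerance = 1e-12)
  # round-trip identity over a log-spaced capacity grid
  p3 <- demographic_params(re = 0.3, K = c(A = 1))
  for (K in 10^seq(0, 6, by = 0.5)) {
    expect_equal(marine_carrying_capacity(terrestrial_dd(K, p3), p3), K,
                 tolerance = 1e-9)
  }
  expect_equal(marine_carrying_capacity(2 * eta, p),
               marine_carrying_capacity(eta, p) / 2, tolerance = 1e-12)
  expect_error(marine_carrying_capacity(0, p), "> 0")
  expect_error(recruitment_rate(-1, 0.1, 0.1, p), ">= 0")
})

test_that("capacity dominance labels regulation with a terrestrial tie rule", {
  d <- capacity_dominance(c(30000, 50000, 10000), c(30000, 30000, 30000))
  expect_equal(d$dominance, c(0, 20000, -20000))
  expect_equal(d$regulation, c("terrestrial", "terrestrial", "marine"))
})

test_that("epizootic-year survival follows colony status", {
  p <- demographic_params(K = c(A = 1000))
  expect_equal(hpai_survival("affected", p), 0.455)
  expect_equal(hpai_survival("unaffected", p), p$phi_ad)
  set.seed(1)
  draws <- hpai_survival(rep("unknown", 500), p)
  expect_true(all(draws >= 0.455 & draws <= 0.94))
  expect_error(hpai_survival("sick", p), "unknown HPAI status")
})

make_two_colony_state <- function(params, P = c(A = 5000, B = 2000)) {
  colony_state(P, 2000L, params)
}

test_that("the annual step conserves individuals and obeys survival limits", {
  params <- demographic_params(alpha0 = 1, beta0 = -7,
                               K = c(A = 50000, B = 40000))
  spec <- model_spec()
  climate <- tibble::tibble(colony_id = c("A", "B"), SST = 0, SLM = 0,
                            nsAT = 0, nsWS = 0, prec = 0)
  st <- make_two_colony_state(params)
  nxt <- step_metapopulation(st, climate, params, spec)
  expect_true(all(nxt$P >= 0), all(nxt$J >= 0))

  # all mortality: everything is gone within one step of each stage
  dead <- demographic_params(alpha0 = 1, phi_ad = 1e-12, phi_juv = 1e-12,
                             K = params$K)
  nxt2 <- step_metapopulation(make_two_colony_state(dead), climate, dead, spec)
  expect_lt(sum(nxt2$P), 1e-6 * sum(st$P))
  expect_lt(sum(nxt2$J[, -1]), 1e-6 * sum(st$J))

  # movement conserves the eligible pool: total pre-breeders reaching
  # breeding age either recruit or re-enter the oldest class
  J <- st$J
  eligible_total <- params$phi_juv * (sum(J[, 4]) + sum(J[, 5]))
  recruits <- sum(nxt$P) - params$phi_ad * sum(st$P)
  retained <- sum(nxt$J[, 5])
  expect_equal(recruits + retained, eligible_total, tolerance = 1e-6)
})

test_that("deterministic dynamics converge to a stationary size below capacity", {
  params <- demographic_params(alpha0 = 1, beta0 = -6,
                               K = c(A = 30000, B = 3000))
  spec <- model_spec()
  climate <- tidyr::crossing(colony_id = c("A", "B"), year = 2000:2219) |>
    dplyr::mutate(SST = 0, SLM = 0, nsAT = 0, nsWS = 0, prec = 0)
  st <- colony_state(c(A = 1000, B = 200), 2000L, params)
  traj <- simulate_metapopulation(st, climate, params, spec, n_years = 219)
  eta <- plogis(-6)
  C <- marine_carrying_capacity(eta, params)
  cap <- pmin(params$K, C)
  last <- dplyr::filter(traj, year >= 2210) |>
    dplyr::arrange(colony_id, year)
  for (cid in c("A", "B")) {
    Pl <- last$P[last$colony_id == cid]
    # stationary: negligible year-on-year change
    expect_lt(max(abs(diff(Pl))) / Pl[1], 1e-4)
    # never exceeds the binding capacity by more than the recruitment-tail
    # tolerance (a few logit widths of the settlement curve, ~ 4/alpha)
    expect_lt(Pl[1], cap[[cid]] * (1 + 4 / params$alpha_const))
    expect_gt(Pl[1], 0.5 * cap[[cid]])
  }
})

test_that("compiled simulator agrees with the plain-R process step", {
  study <- tiny_study(seed = 3, n_colonies = 4, years = 1995:2016)
  bd <- metapopclim:::build_model_data(fit_data(study), study$spec_true,
                                       study$params_true)
  pt <- study$params_true
  nat <- setNames(numeric(length(bd$par_names)), bd$par_names)
  nat["alpha0"] <- pt$alpha0
  nat["alpha_nsAT"] <- pt$alpha_lin[["nsAT"]]
  nat["alpha_nsAT2"] <- pt$alpha_quad[["nsAT"]]
  nat["alpha_prec"] <- pt$alpha_lin[["prec"]]
  nat["beta0"] <- pt$beta0
  nat["beta_SST"] <- pt$beta_lin[["SST"]]
  nat["sigma_b"] <- pt$sigma_b
  nat["sigma_obs"] <- pt$sigma_obs
  nat[paste0("K_", study$colonies$colony_id)] <- pt$K
  nat[paste0("P0_", study$colonies$colony_id)] <-
    0.2 * pt$K[study$colonies$colony_id]
  nat[paste0("eps_", names(study$eps_true))] <- study$eps_true
  v <- metapopclim:::to_sampling_scale(nat, bd)
  sim <- metapopclim:::mpc_simulate_cpp(bd$md, v)
  latP <- tidyr::pivot_wider(study$latent[, c("colony_id", "year", "P")],
                             names_from = "year", values_from = "P")
  Pr <- as.matrix(latP[, -1])
  expect_lt(max(abs(sim$P - Pr) / pmax(Pr, 1)), 1e-6)
  # and the compiled likelihood matches the R observation-density sum
  llr <- log_likelihood(study$census, study$fecundity,
                        dplyr::select(study$latent, "colony_id", "year",
                                      "P", "b"),
                        pt)
  expect_equal(sim$loglik, llr, tolerance = 1e-6)
})

test_that("marine capacity falls as SST rises under a positive coefficient", {
  p <- table_params()
  s <- best_spec()
  z <- seq(-2, 2, by = 0.25)
  C <- marine_carrying_capacity(
    marine_dd(tibble::tibble(SST = z, SLM = 0, nsAT = 0, nsWS = 0, prec = 0),
              p, s), p)
  expect_true(all(diff(C) < 0))
})
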