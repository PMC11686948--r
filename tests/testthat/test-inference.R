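# Likelihood, prior, diagnostics, DIC and the MCMC engine.

test_that("observation log likelihood matches hand-summed densities", {
  p <- demographic_params(sigma_obs = 0.2, K = c(A = 1000, B = 500))
  latent <- tibble::tibble(colony_id = c("A", "A", "B"),
                           year = c(2000L, 2001L, 2000L),
                           P = c(800, 850, 300), b = c(0.6, 0.7, 0.5))
  census <- tibble::tibble(colony_id = c("A", "B"), year = c(2000L, 2000L),
                           aos_count = c(812L, 0L))
  fec <- tibble::tibble(colony_id = "A", year = 2001L, nests = 50L,
                        chicks = 33L)
  # independent scalar-density oracle
  by_hand <- dnorm(log(812), log(800), 0.2, log = TRUE) +
    dnorm(log(0.5), log(300), 0.2, log = TRUE) +
    dbinom(33, 50, 0.7, log = TRUE)
  expect_equal(log_likelihood(census, fec, latent, p), by_hand,
               tolerance = 1e-9)
  # no observations at all
  expect_equal(log_likelihood(census[0, ], fec[0, ], latent, p), 0)
  # a census point sitting on the latent state with unit noise
  p1 <- demographic_params(sigma_obs = 1, K = c(A = 1000))
  cen1 <- tibble::tibble(colony_id = "A", year = 2000L, aos_count = 800L)
  expect_equal(log_likelihood(cen1, NULL, latent, p1),
               dnorm(0, 0, 1, log = TRUE), tolerance = 1e-9)
  expect_error(log_likelihood(dplyr::mutate(cen1, year = 1950L), NULL,
                              latent, p1), "cover")
})

test_that("the prior follows the stated structure and sign constraints", {
  p <- table_params()
  s <- best_spec()
  # Gamma(1,1) magnitude = Exponential(1): log density at 0.848 is -0.848
  expect_equal(stats::dexp(0.848, 1, log = TRUE), -0.848, tolerance = 1e-12)
  lp <- log_prior(p, s)
  expect_true(is.finite(lp))
  # negative quadratic magnitude is outside the support
  p_bad <- p
  p_bad$alpha_quad["nsAT"] <- -0.1
  expect_equal(log_prior(p_bad, s), -Inf)
  # an all-zero linear coefficient contributes the standard-normal mode
  p0 <- demographic_params(beta_lin = c(SST = 0), K = c(A = 1000))
  s0 <- model_spec(recruitment = c(SST = 1))
  delta <- log_prior(p0, s0) -
    log_prior(demographic_params(beta_lin = c(SST = 1), K = c(A = 1000)), s0)
  expect_equal(delta, dnorm(0, log = TRUE) - dnorm(1, log = TRUE),
               tolerance = 1e-12)
})

test_that("Gelman-Rubin matches a brute-force evaluation and flags divergence", {
  set.seed(1)
  chains <- lapply(1:4, function(i) {
    m <- cbind(a = rnorm(100), b = rnorm(100, 0, 2))
    m
  })
  got <- gelman_rubin(chains)
  # independent brute-force formula evaluation
  for (j in 1:2) {
    x <- sapply(chains, function(m) m[, j])
    n <- nrow(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    expect_equal(got$rhat[j], sqrt(((n - 1) / n * W + B / n) / W),
                 tolerance = 1e-12)
  }
  # identical chains: between-chain variance zero, statistic at most 1
  same <- lapply(1:3, function(i) cbind(a = sin(1:50)))
  expect_lte(gelman_rubin(same)$rhat, 1 + 1e-6)
  # chains in different places blow the diagnostic up
  apart <- list(cbind(a = rnorm(100, 0, 1)), cbind(a = rnorm(100, 10, 1)))
  expect_gt(gelman_rubin(apart)$rhat, 1.1)
  expect_error(gelman_rubin(apart[1]), "2 chains")
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  # coda applies finite-sample degrees-of-freedom corrections on top of the
  # classic statistic; at large chain length the two coincide
  set.seed(42)
  chains <- lapply(1:3, function(i) {
    cbind(theta = rnorm(5000, mean = 0.05 * i))
  })
  ours <- gelman_rubin(chains)$rhat
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1, "Point est."]
  expect_equal(ours, ref, tolerance = 0.01)
})

test_that("DIC components behave on degenerate and conjugate toys", {
  # degenerate posterior: all draws identical, no effective parameters
  d <- dic(rep(123.4, 50), deviance_at_mean = 123.4)
  expect_equal(d$pd, 0)
  expect_equal(d$dic, 123.4)
  expect_error(dic(rep(1, 10), deviance_at_mean = 1), "30 retained")

  # Normal toy with known posterior: pD approximates the number of means
  set.seed(7)
  n_groups <- 3
  n_obs <- 50
  y <- matrix(rnorm(n_groups * n_obs, mean = c(-1, 0, 1)), nrow = n_obs,
              byrow = TRUE)
  ybar <- colMeans(y)
  n_draws <- 4000
  theta <- sapply(seq_len(n_groups), function(j) {
    rnorm(n_draws, ybar[j], 1 / sqrt(n_obs)) # flat-prior posterior
  })
  dev <- sapply(seq_len(n_draws), function(k) {
    -2 * sum(dnorm(t(y), theta[k, ], 1, log = TRUE))
  })
  dev_at_mean <- -2 * sum(dnorm(t(y), colMeans(theta), 1, log = TRUE))
  out <- dic(dev, deviance_at_mean = dev_at_mean)
  expect_equal(out$pd, n_groups, tolerance = 0.35)
})

test_that("the reference AMWG sampler recovers a conjugate Normal posterior", {
  set.seed(3)
  y <- rnorm(25, 1.7, 1)
  n <- length(y)
  post_mean <- sum(y) / (n + 1)        # N(0,1) prior, unit-variance data
  post_sd <- 1 / sqrt(n + 1)
  lp <- function(th) -0.5 * th^2 - 0.5 * sum((y - th)^2)
  draws <- amwg_sample(lp, c(theta = 0), n_iter = 6000, burn = 1000)
  mcse <- sd(draws) / sqrt(200) # conservative effective-size guess
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 0.01)
  expect_equal(sd(draws), post_sd, tolerance = 0.15)
})

test_that("the fitting engine is seed-reproducible and shaped correctly", {
  study <- tiny_study(seed = 5)
  f1 <- quick_fit(study, iter = 400, burn = 100, thin = 5, seed = 9)
  f2 <- quick_fit(study, iter = 400, burn = 100, thin = 5, seed = 9)
  expect_identical(f1$draws$value, f2$draws$value)
  f3 <- quick_fit(study, iter = 400, burn = 100, thin = 5, seed = 10)
  expect_false(identical(f1$draws$value, f3$draws$value))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat") %in%
                    names(tidy(f1))))
  expect_true(all(tidy(f1, "all")$conf.low <= tidy(f1, "all")$estimate))
  expect_true(all(c("colony_id", "year", "median") %in% names(f1$latent)))
  g <- glance(f1)
  expect_equal(g$n_chains, 2)
  expect_equal(g$model, study$spec_true$id)
})

test_that("with no observations the sampler returns the prior", {
  study <- tiny_study(seed = 6)
  empty <- fit_data(study)
  empty$census <- empty$census[0, ]
  empty$fecundity <- empty$fecundity[0, ]
  fit <- suppressWarnings(run_mcmc(empty, model_spec(recruitment = c(SST = 1)),
                                   chains = 2, iter = 4000, burn = 1000,
                                   thin = 5, seed = 2))
  d <- fit$draws
  # free linear coefficient: standard normal prior
  bs <- d$value[d$parameter == "beta_SST"]
  expect_lt(abs(mean(bs)), 0.15)
  expect_equal(sd(bs), 1, tolerance = 0.15)
  # capacity prior: log-normal around the expert value with 20 percent CV
  k1 <- d$value[d$parameter == paste0("K_", study$colonies$colony_id[1])]
  expect_equal(mean(log(k1)), log(study$colonies$K_expert[1]),
               tolerance = 0.05)
  expect_equal(sd(log(k1)), 0.2, tolerance = 0.05)
})

test_that("model selection ranks by DIC with the null-based delta", {
  study <- tiny_study(seed = 8, n_colonies = 3, years = 1995:2014)
  specs <- list(model_spec(), study$spec_true)
  tab <- suppressWarnings(select_model(fit_data(study), specs, chains = 2,
                                       iter = 600, burn = 200, thin = 5,
                                       seed = 4))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("id", "dic", "delta_dic", "converged") %in% names(tab)))
  # delta is anchored at the null: the null row has delta zero
  expect_equal(tab$delta_dic[tab$id == "m0.00"], 0)
  # ranking is invariant to the order the specs are supplied in
  tab2 <- suppressWarnings(select_model(fit_data(study), rev(specs),
                                        chains = 2, iter = 600, burn = 200,
                                        thin = 5, seed = 4))
  expect_equal(tab$id, tab2$id)
  expect_equal(tab$dic, tab2$dic, tolerance = 1e-9)
})

test_that("posterior latent states track the true trajectory", {
  study <- simulate_study(n_colonies = 4, years = 1990:2016, seed = 23)
  fit <- suppressWarnings(run_mcmc(fit_data(study), study$spec_true,
                                   chains = 2, iter = 2500, burn = 500,
                                   thin = 10, seed = 23))
  obs <- dplyr::semi_join(study$latent, study$census,
                          by = c("colony_id", "year"))
  comp <- dplyr::inner_join(obs, fit$latent, by = c("colony_id", "year"))
  post_sd <- (comp$upper95 - comp$lower95) / 3.92
  ok <- abs(comp$median - comp$P) <= 2 * post_sd
  expect_gte(mean(ok), 0.9)
})
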