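# Small synthetic fixtures shared across test files. Everything is built in
# code from a seed; nothing is read from disk.

tiny_study <- function(seed = 1, n_colonies = 3, years = 1990:2014, ...) {
  simulate_study(n_colonies = n_colonies, years = years, seed = seed, ...)
}

fit_data <- function(study) {
  list(census = study$census, fecundity = study$fecundity,
       climate = study$climate, colonies = study$colonies)
}

quick_fit <- function(study, spec = study$spec_true, chains = 2, iter = 600,
                      burn = 200, thin = 5, seed = 1, ...) {
  suppressWarnings(run_mcmc(fit_data(study), spec, chains = chains,
                            iter = iter, burn = burn, thin = thin,
                            seed = seed, ...))
}

# parameters matching the published posterior medians of the best model
table_params <- function(K = c(A = 10000)) {
  demographic_params(alpha0 = 0.969,
                     alpha_lin = c(nsAT = 1.546, prec = 0.139),
                     alpha_quad = c(nsAT = 0.848),
                     beta0 = -6.619, beta_lin = c(SST = 0.881),
                     K = K)
}

best_spec <- function() {
  model_spec(fecundity = c(nsAT = 2, prec = 1), recruitment = c(SST = 1))
}

# one-row covariate set with all five covariates at zero unless overridden
zrow <- function(...) {
  x <- setNames(rep(0, 5), mpc_covariates())
  over <- c(...)
  x[names(over)] <- over
  x
}
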