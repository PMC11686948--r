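# Bayesian fitting of the state-space model. The process is deterministic
# given (parameters, annual fecundity noise eps_t, initial colony sizes), so
# the sampler explores parameters + eps series + initial sizes jointly with
# an adaptive random-walk Metropolis-within-Gibbs scheme (compiled core in
# src/mpc.cpp), plus a likelihood-free "ridge" move that trades the
# fecundity intercept against the whole eps series.

#' Prior settings of the hierarchical model
#'
#' Linear covariate coefficients get standard-normal priors; coefficients of
#' downward parabolas (the linear and quadratic terms of an order-2
#' covariate) get Gamma(shape 1, rate 1) priors on their magnitude, imposing
#' the sign constraint. Intercepts get a wide normal, noise SDs half-normal
#' priors, terrestrial capacities log-normal priors centred on the
#' expert-elicited value with 20 percent CV, initial colony sizes log-normal
#' priors centred on the earliest census, and the epizootic-year survival of
#' unknown-status colonies a Uniform(0.455, 0.94) prior.
#'
#' @param intercept_sd SD of the normal prior on the two intercepts.
#' @param coef_sd SD of the normal prior on unconstrained linear
#'   coefficients.
#' @param sigma_b_scale,sigma_obs_scale Half-normal scales for the process
#'   and observation noise SDs.
#' @param K_cv Log-scale SD (approximately the CV) of the carrying-capacity
#'   prior around the expert value.
#' @param P0_sd Log-scale SD of the initial-size prior.
#' @return A named list of prior hyper-parameters.
#' @export
prior_settings <- function(intercept_sd = 5, coef_sd = 1,
                           sigma_b_scale = 1, sigma_obs_scale = 1,
                           K_cv = 0.2, P0_sd = 1) {
  list(intercept_sd = intercept_sd, coef_sd = coef_sd,
       sigma_b_scale = sigma_b_scale, sigma_obs_scale = sigma_obs_scale,
       K_cv = K_cv, P0_sd = P0_sd)
}

# term table with sign-constraint flags: every term of an order-2 covariate
# (both its linear and quadratic part) is constrained positive
term_table <- function(terms) {
  if (!nrow(terms)) {
    return(tibble::tibble(covariate = character(), order = integer(),
                          constrained = logical(), negative = logical()))
  }
  quad_cov <- terms$covariate[terms$order == 2]
  terms |>
    dplyr::mutate(constrained = .data$covariate %in% quad_cov,
                  negative = .data$order == 2)
}

# Assemble the compiled-core data list and the parameter metadata.
# data: list(census, fecundity, climate, colonies); years: fitting window.
build_model_data <- function(data, spec, params, years = NULL,
                             priors = prior_settings()) {
  colonies <- tibble::as_tibble(data$colonies)
  ids <- colonies$colony_id
  n <- length(ids)
  wide <- climate_wide(data$climate, scenario = "hindcast")
  if (is.null(years)) years <- seq(min(wide$year), max(wide$year))
  years <- sort(years)
  T <- length(years)
  wide <- dplyr::filter(wide, .data$year %in% years)

  covmat <- function(cov) {
    if (!cov %in% names(wide)) {
      abort(paste0("covariate `", cov, "` missing from the climate series"))
    }
    m <- matrix(NA_real_, n, T, dimnames = list(ids, years))
    idx <- cbind(match(wide$colony_id, ids), match(wide$year, years))
    m[idx] <- wide[[cov]]
    if (anyNA(m)) abort("climate series does not cover every colony-year")
    m
  }
  ft <- term_table(spec$fecundity_terms)
  rt <- term_table(spec$recruitment_terms)
  Zf <- purrr::map2(ft$covariate, ft$order, ~ covmat(.x)^.y)
  Zr <- purrr::map2(rt$covariate, rt$order, ~ covmat(.x)^.y)

  census <- tibble::as_tibble(data$census)
  fec <- tibble::as_tibble(data$fecundity %||%
                             tibble::tibble(colony_id = character(),
                                            year = integer(), nests = integer(),
                                            chicks = integer()))
  for (df_name in c("census", "fec")) {
    df <- get(df_name)
    if (nrow(df)) {
      if (any(!df$colony_id %in% ids)) abort("observation for unknown colony")
      if (any(!df$year %in% years)) {
        abort("observation outside the fitting window; states must cover all observed colony-years")
      }
    }
  }
  hpai_t <- match(params$hpai_year, years)
  codes <- c(affected = 0L, unaffected = 1L, unknown = 2L)
  hpai_code <- codes[colonies$hpai_status %||% rep("unaffected", n)]

  # initial-size prior centred on the earliest census (fallback K/10)
  first_cen <- census |>
    dplyr::slice_min(.data$year, n = 1, by = "colony_id", with_ties = FALSE)
  P0_mu <- log(pmax(colonies$K_expert / 10, 1))
  m <- match(ids, first_cen$colony_id)
  hit <- !is.na(m)
  P0_mu[hit] <- log(pmax(first_cen$aos_count[m[hit]], 1))

  md <- list(
    n = n, T = T, a_first = params$a_first,
    phi_ad = params$phi_ad, phi_juv = params$phi_juv, re = params$re,
    alpha_const = params$alpha_const, rho = params$rho,
    chick_pair = params$chick_pair,
    Zf = Zf, Zr = Zr,
    f_con = as.integer(ft$constrained), r_con = as.integer(rt$constrained),
    f_neg = as.integer(ft$negative), r_neg = as.integer(rt$negative),
    cen_c = match(census$colony_id, ids) - 1L,
    cen_t = match(census$year, years) - 1L,
    cen_logy = log(ifelse(census$aos_count == 0, 0.5, census$aos_count)),
    fec_c = match(fec$colony_id, ids) - 1L,
    fec_t = match(fec$year, years) - 1L,
    fec_nests = as.numeric(fec$nests), fec_chicks = as.numeric(fec$chicks),
    fec_lch = lchoose(as.numeric(fec$nests), as.numeric(fec$chicks)),
    hpai_t = ifelse(is.na(hpai_t), -1L, hpai_t - 1L),
    hpai_code = unname(hpai_code),
    hpai_phi_affected = params$hpai_phi_affected,
    hpai_lo = params$hpai_phi_affected, hpai_hi = params$hpai_phi_max,
    int_sd = priors$intercept_sd, coef_sd = priors$coef_sd,
    sb_scale = priors$sigma_b_scale, so_scale = priors$sigma_obs_scale,
    K_sd = priors$K_cv, P0_sd = priors$P0_sd,
    K_mu = log(colonies$K_expert), P0_mu = P0_mu
  )

  coef_name <- function(prefix, tt) {
    if (!nrow(tt)) return(character())
    paste0(prefix, "_", tt$covariate, ifelse(tt$order == 2, "2", ""))
  }
  unk <- ids[hpai_code == 2L & md$hpai_t >= 0]
  par_names <- c("alpha0", coef_name("alpha", ft), "beta0", coef_name("beta", rt),
                 "sigma_b", "sigma_obs", paste0("K_", ids), paste0("P0_", ids),
                 if (length(unk)) paste0("phi", params$hpai_year, "_", unk),
                 paste0("eps_", years))
  list(md = md, par_names = par_names, ids = ids, years = years,
       ft = ft, rt = rt, n_unknown = length(unk))
}

# demographically plausible starting point on the sampling scale; the
# fecundity side is initialised from a binomial GLM on the monitoring
# records (standard informed-inits practice), the recruitment side at the
# scale of large-colony marine capacities
initial_values <- function(bd, data) {
  md <- bd$md
  fec <- data$fecundity
  kf <- length(md$f_con)
  a0 <- 0
  fcoef <- ifelse(md$f_con == 1, log(0.3), 0)
  if (!is.null(fec) && nrow(fec) >= max(10, 2 * (kf + 1)) &&
      sum(fec$nests) > 0) {
    a0 <- logit(pmin(pmax(sum(fec$chicks) / sum(fec$nests), 0.05), 0.95))
    fec_t <- md$fec_t + 1L
    fec_c <- md$fec_c + 1L
    X <- vapply(md$Zf, function(Z) Z[cbind(fec_c, fec_t)],
                numeric(length(fec_c)))
    est <- tryCatch({
      gfit <- stats::glm.fit(cbind(1, X),
                             cbind(md$fec_chicks,
                                   md$fec_nests - md$fec_chicks),
                             family = stats::binomial())
      coef(gfit)
    }, error = function(e) NULL)
    if (!is.null(est) && all(is.finite(est))) {
      a0 <- est[1]
      raw <- est[-1]
      for (k in seq_len(kf)) {
        fcoef[k] <- if (md$f_con[k] == 1) {
          sign_ok <- if (md$f_neg[k] == 1) -raw[k] else raw[k]
          log(max(sign_ok, 0.05))
        } else raw[k]
      }
    }
  }
  v <- c(a0,
         fcoef,
         -6, # marine DD at the scale of large-colony capacities
         ifelse(md$r_con == 1, log(0.3), 0),
         log(0.3), log(0.2),
         md$K_mu, md$P0_mu,
         rep(0, bd$n_unknown),
         rep(0, md$T))
  stopifnot(length(v) == length(bd$par_names))
  v
}

# natural -> sampling scale for one named vector (layout of bd$par_names)
to_sampling_scale <- function(nat, bd) {
  md <- bd$md
  kf <- length(md$f_con); kr <- length(md$r_con)
  n <- md$n
  v <- nat
  i <- (1 + seq_len(kf))[md$f_con == 1]
  v[i] <- log(nat[i])
  j <- (1 + kf + 1 + seq_len(kr))[md$r_con == 1]
  v[j] <- log(nat[j])
  base <- 1 + kf + 1 + kr
  v[base + 1:2] <- log(nat[base + 1:2])                     # sigmas
  v[base + 2 + seq_len(2 * n)] <- log(nat[base + 2 + seq_len(2 * n)]) # K, P0
  if (bd$n_unknown > 0) {
    h <- base + 2 + 2 * n + seq_len(bd$n_unknown)
    u <- (nat[h] - md$hpai_lo) / (md$hpai_hi - md$hpai_lo)
    v[h] <- logit(pmin(pmax(u, 1e-10), 1 - 1e-10))
  }
  v
}

#' Fit the state-space metapopulation model by MCMC
#'
#' Runs parallel-in-seed adaptive Metropolis-within-Gibbs chains over the
#' model parameters, the annual logit-scale fecundity noise and the initial
#' colony sizes (the process is deterministic given these, so they carry all
#' latent-state uncertainty). Returns posterior draws, per-parameter
#' Gelman-Rubin diagnostics, DIC and latent-state summaries.
#'
#' @param data List (or [simulate_study()] result) with elements `census`
#'   (`colony_id`, `year`, `aos_count`), `fecundity` (`colony_id`, `year`,
#'   `nests`, `chicks`), `climate` (standardized long series containing the
#'   `"hindcast"` scenario) and `colonies` (`colony_id`, `K_expert`,
#'   `hpai_status`).
#' @param spec A [model_spec()].
#' @param params A [demographic_params()] supplying the fixed demographic
#'   constants (`phi_ad`, `phi_juv`, `a_first`, `re`, `alpha_const`, `rho`,
#'   `chick_pair`); its coefficient fields are ignored (they are estimated).
#' @param chains Number of chains (default 4), seeded `seed + chain - 1`.
#' @param iter,burn,thin Iterations per chain, burn-in and thinning; the
#'   full-scale defaults (100000 / 15000 / 200) suit overnight runs, while
#'   desk-scale checks use much smaller values.
#' @param years Fitting-window years; default spans the hindcast climate.
#' @param priors [prior_settings()].
#' @param seed Integer seed.
#' @param rhat_threshold Convergence is declared when every parameter's
#'   potential scale reduction factor is below this (default 1.1).
#' @return An object of class `metapop_fit` with elements `draws` (tibble:
#'   `chain`, `draw`, `parameter`, `value`; natural scale), `summary`
#'   (median, 95 percent credible interval and R-hat per parameter),
#'   `latent` (posterior median and interval of colony size per
#'   colony-year), `dic` (list `dic`, `dbar`, `pd`), `converged`, and the
#'   bookkeeping needed by [forecast_scenarios()].
#' @export
run_mcmc <- function(data, spec, params = demographic_params(K = setNames(
                       data$colonies$K_expert, data$colonies$colony_id)),
                     chains = 4, iter = 100000, burn = 15000, thin = 200,
                     years = NULL, priors = prior_settings(), seed = 1,
                     rhat_threshold = 1.1) {
  stopifnot(chains >= 1, iter > burn, thin >= 1)
  bd <- build_model_data(data, spec, params, years = years, priors = priors)
  init <- initial_values(bd, data)
  p <- length(init)

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    v0 <- init + rnorm(p, 0, 0.05)
    chain_out[[ch]] <- mpc_fit_cpp(bd$md, v0, as.integer(iter),
                                   as.integer(burn), as.integer(thin))
  }
  nat_chains <- purrr::map(chain_out, function(x) {
    m <- x$draws
    colnames(m) <- bd$par_names
    m
  })
  draws <- purrr::imap_dfr(nat_chains, function(m, ch) {
    tibble::tibble(chain = as.integer(ch),
                   draw = rep(seq_len(nrow(m)), times = ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  })
  rhat <- if (chains >= 2) gelman_rubin(nat_chains) else {
    tibble::tibble(parameter = bd$par_names, rhat = NA_real_)
  }
  all_nat <- do.call(rbind, nat_chains)
  qs <- apply(all_nat, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  summary <- tibble::tibble(parameter = bd$par_names,
                            median = qs[1, ], lower95 = qs[2, ],
                            upper95 = qs[3, ]) |>
    dplyr::left_join(rhat, by = "parameter")

  latent_all <- do.call(rbind, purrr::map(chain_out, "latentP"))
  lat_q <- apply(latent_all, 2, quantile, probs = c(0.5, 0.025, 0.975),
                 names = FALSE)
  latent <- tibble::tibble(
    colony_id = rep(bd$ids, times = bd$md$T),
    year = rep(bd$years, each = bd$md$n),
    median = lat_q[1, ], lower95 = lat_q[2, ], upper95 = lat_q[3, ]
  )
  loglik_draws <- unlist(purrr::map(chain_out, "loglik"))

  fit <- structure(
    list(draws = draws, summary = summary, latent = latent,
         nat_chains = nat_chains, latent_chains = purrr::map(chain_out, "latentP"),
         loglik = loglik_draws, bd = bd, spec = spec, params = params,
         data = data,
         settings = list(chains = chains, iter = iter, burn = burn,
                         thin = thin, seed = seed),
         rhat_threshold = rhat_threshold),
    class = "metapop_fit"
  )
  fit$converged <- isTRUE(all(summary$rhat[is.finite(summary$rhat)] <
                                rhat_threshold)) ||
    all(!is.finite(summary$rhat))
  fit$dic <- tryCatch(dic(fit), error = function(e) {
    warn(conditionMessage(e)); NULL
  })
  fit
}

#' @export
print.metapop_fit <- function(x, ...) {
  cat("<metapop_fit>", x$spec$id, "|", x$settings$chains, "chains x",
      x$settings$iter, "iterations (burn-in", x$settings$burn, ", thin",
      x$settings$thin, ")\n")
  if (!is.null(x$dic)) {
    cat("  DIC", round(x$dic$dic, 1), " (Dbar", round(x$dic$dbar, 1),
        ", pD", round(x$dic$pd, 1), ")\n")
  }
  cat("  converged:", x$converged, " (max R-hat",
      round(max(x$summary$rhat[is.finite(x$summary$rhat)], na.rm = TRUE), 3),
      ")\n")
  keep <- !grepl("^(eps_|P0_|K_)", x$summary$parameter)
  print(x$summary[keep, ], n = 20)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic multi-chain convergence diagnostic: the ratio of the pooled
#' to the within-chain posterior scale estimate. Values near 1 indicate the
#' chains agree; convergence is conventionally declared below 1.1.
#'
#' @param draws Either a list of equally sized draws matrices (iterations x
#'   parameters, one per chain) or a tidy tibble with columns `chain`,
#'   `draw`, `parameter`, `value`.
#' @return Tibble (`parameter`, `rhat`). With identical chains the
#'   between-chain variance is zero and the statistic is at most 1.
#' @export
gelman_rubin <- function(draws) {
  if (is.data.frame(draws)) {
    mats <- draws |>
      dplyr::arrange(.data$chain, .data$parameter, .data$draw) |>
      (\(d) split(d, d$chain))() |>
      purrr::map(function(d) {
        m <- matrix(d$value, ncol = dplyr::n_distinct(d$parameter))
        colnames(m) <- unique(d$parameter)
        m
      })
  } else {
    mats <- draws
  }
  if (length(mats) < 2) abort("at least 2 chains are required for R-hat")
  dims <- purrr::map(mats, dim)
  if (length(unique(dims)) != 1) abort("chains must have equal dimensions")
  n <- nrow(mats[[1]]); m <- length(mats)
  pars <- colnames(mats[[1]]) %||% paste0("par", seq_len(ncol(mats[[1]])))
  rhat <- purrr::map_dbl(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(mats, function(mm) mm[, j], numeric(n))
    W <- mean(apply(x, 2, var))
    B_over_n <- var(colMeans(x))
    if (!is.finite(W) || (W == 0 && B_over_n == 0)) return(1)
    if (W == 0) return(Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  tibble::tibble(parameter = pars, rhat = rhat)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters, the
#' deviance focus being the observation level conditional on the latent
#' states. `pD` can come out negative for badly behaved posteriors; it is
#' then reported with a warning rather than suppressed.
#'
#' @param x A `metapop_fit`, or a numeric vector of per-draw deviances.
#' @param ... Unused for fits; for the default method, pass
#'   `deviance_at_mean`.
#' @return List with `dic`, `dbar`, `pd`.
#' @export
dic <- function(x, ...) UseMethod("dic")

#' @rdname dic
#' @param deviance_at_mean Deviance evaluated at the posterior mean of the
#'   sampled quantities.
#' @export
dic.default <- function(x, deviance_at_mean, ...) {
  if (length(x) < 30) abort("at least 30 retained draws are required for DIC")
  dbar <- mean(x)
  pd <- dbar - deviance_at_mean
  if (is.finite(pd) && pd < 0) {
    warn(sprintf("negative effective number of parameters (pD = %.2f)", pd))
  }
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

#' @rdname dic
#' @export
dic.metapop_fit <- function(x, ...) {
  if (length(x$loglik) < 30) {
    abort("at least 30 retained draws are required for DIC")
  }
  theta_bar <- colMeans(do.call(rbind, x$nat_chains))
  v_bar <- to_sampling_scale(theta_bar, x$bd)
  d_hat <- -2 * mpc_loglik_cpp(x$bd$md, v_bar)
  dic.default(-2 * x$loglik, d_hat)
}

#' Observation-level log likelihood
#'
#' Sums the census and fecundity observation densities given a latent
#' trajectory: `log(count) ~ Normal(log P, sigma_obs)` (zero counts entered
#' as `log 0.5`) and `chicks ~ Binomial(nests, b)`. With no observations the
#' log likelihood is 0 by convention.
#'
#' @param census Tibble (`colony_id`, `year`, `aos_count`); may be empty.
#' @param fecundity Tibble (`colony_id`, `year`, `nests`, `chicks`); may be
#'   empty or `NULL`.
#' @param latent Tibble (`colony_id`, `year`, `P`, `b`) covering every
#'   observed colony-year.
#' @param params A [demographic_params()] (uses `sigma_obs`).
#' @return Scalar log likelihood; non-finite values trigger a warning.
#' @export
log_likelihood <- function(census, fecundity, latent, params) {
  latent <- tibble::as_tibble(latent)
  ll <- 0
  if (!is.null(census) && nrow(census)) {
    j <- dplyr::inner_join(tibble::as_tibble(census), latent,
                           by = c("colony_id", "year"))
    if (nrow(j) < nrow(census)) abort("latent states must cover all observed colony-years")
    logy <- log(ifelse(j$aos_count == 0, 0.5, j$aos_count))
    ll <- ll + sum(dnorm(logy, log(pmax(j$P, 1e-300)), params$sigma_obs,
                         log = TRUE))
  }
  if (!is.null(fecundity) && nrow(fecundity)) {
    j <- dplyr::inner_join(tibble::as_tibble(fecundity), latent,
                           by = c("colony_id", "year"))
    if (nrow(j) < nrow(fecundity)) abort("latent states must cover all observed colony-years")
    ll <- ll + sum(dbinom(j$chicks, j$nests, j$b, log = TRUE))
  }
  if (!is.finite(ll)) warn("non-finite log likelihood")
  ll
}

#' Log prior density of the demographic parameters
#'
#' The joint prior over the natural-scale parameters: Normal(0, 1) on
#' unconstrained linear coefficients, Gamma(1, 1) (i.e. Exponential(1)) on
#' the magnitudes of sign-constrained parabola coefficients, wide normals on
#' the intercepts, half-normals on the noise SDs and log-normals on the
#' carrying capacities around their expert-elicited values. Out-of-support
#' values (negative magnitudes) give `-Inf`.
#'
#' @param params A [demographic_params()] holding the values to evaluate.
#' @param spec A [model_spec()].
#' @param K_expert Named expert point values for the capacities (default:
#'   `params$K`, i.e. evaluated at the prior mode).
#' @param priors [prior_settings()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, spec, K_expert = params$K,
                      priors = prior_settings()) {
  lp <- dnorm(params$alpha0, 0, priors$intercept_sd, log = TRUE) +
    dnorm(params$beta0, 0, priors$intercept_sd, log = TRUE)
  coef_lp <- function(tt, lin, quad) {
    out <- 0
    for (i in seq_len(nrow(tt))) {
      val <- if (tt$order[i] == 1) lin[[tt$covariate[i]]] else quad[[tt$covariate[i]]]
      if (is.null(val) || is.na(val)) abort("missing coefficient for a spec term")
      out <- out + if (tt$constrained[i]) {
        if (val < 0) -Inf else stats::dexp(val, 1, log = TRUE)
      } else {
        dnorm(val, 0, priors$coef_sd, log = TRUE)
      }
    }
    out
  }
  lp <- lp + coef_lp(term_table(spec$fecundity_terms), params$alpha_lin,
                     params$alpha_quad)
  lp <- lp + coef_lp(term_table(spec$recruitment_terms), params$beta_lin,
                     params$beta_quad)
  halfnorm <- function(s, scale) {
    if (s < 0) return(-Inf)
    log(2) + dnorm(s, 0, scale, log = TRUE)
  }
  lp <- lp + halfnorm(params$sigma_b, priors$sigma_b_scale) +
    halfnorm(params$sigma_obs, priors$sigma_obs_scale)
  lp + sum(stats::dlnorm(params$K, log(K_expert[names(params$K)]),
                         priors$K_cv, log = TRUE))
}

#' Fit and rank a suite of candidate model structures
#'
#' Fits each candidate with [run_mcmc()] and tabulates DIC against the null
#' (intercept-only) model. `delta_dic` is `DIC_null - DIC_model`, so the
#' best-supported model has the highest `delta_dic`; the `best` attribute
#' holds the lowest-DIC converged model (all models, if none converged).
#'
#' @param data As in [run_mcmc()].
#' @param specs A list of [model_spec()] objects or a tibble with a `spec`
#'   list-column (as returned by [enumerate_models()]).
#' @param ... Settings forwarded to [run_mcmc()] (`chains`, `iter`, `burn`,
#'   `thin`, `seed`, ...).
#' @return Tibble (`id`, `fecundity`, `recruitment`, `dic`, `delta_dic`,
#'   `pd`, `max_rhat`, `converged`), sorted by DIC, with attributes `best`
#'   (id) and `fits` (list of fits).
#' @export
select_model <- function(data, specs, ...) {
  if (is.data.frame(specs)) specs <- specs$spec
  if (length(specs) < 1) abort("need at least one model spec")
  fits <- purrr::map(specs, function(sp) run_mcmc(data, sp, ...))
  desc <- function(terms) {
    if (!nrow(terms)) return("-")
    terms |>
      dplyr::summarise(order = max(.data$order), .by = "covariate") |>
      dplyr::mutate(l = paste0(.data$covariate,
                               ifelse(.data$order == 2, "^2", ""))) |>
      dplyr::pull("l") |> paste(collapse = "+")
  }
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      id = f$spec$id,
      fecundity = desc(f$spec$fecundity_terms),
      recruitment = desc(f$spec$recruitment_terms),
      dic = if (is.null(f$dic)) NA_real_ else f$dic$dic,
      pd = if (is.null(f$dic)) NA_real_ else f$dic$pd,
      max_rhat = suppressWarnings(
        max(f$summary$rhat[is.finite(f$summary$rhat)], na.rm = TRUE)),
      converged = f$converged
    )
  })
  null_dic <- tab$dic[tab$id == "m0.00"]
  tab$delta_dic <- if (length(null_dic) == 1) null_dic - tab$dic else NA_real_
  tab <- dplyr::arrange(tab, .data$dic)
  pool <- if (any(tab$converged & !is.na(tab$dic))) {
    dplyr::filter(tab, .data$converged, !is.na(.data$dic))
  } else {
    dplyr::filter(tab, !is.na(.data$dic))
  }
  attr(tab, "best") <- if (nrow(pool)) pool$id[which.min(pool$dic)] else NA_character_
  attr(tab, "fits") <- setNames(fits, purrr::map_chr(fits, ~ .x$spec$id))
  tab
}
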