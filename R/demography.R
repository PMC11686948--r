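# Closed-form demographic rates and the one-step metapopulation update.
#
# All rates live on the logit scale: fecundity and marine density dependence
# are logit-linear (optionally quadratic) in standardized climate covariates;
# recruitment decays logistically with colony size through whichever density
# dependence (terrestrial or marine) is the stronger.

# Evaluate a logit-linear predictor with sign-constrained quadratics.
# x: data frame (or named vector) of standardized covariate values;
# terms: tibble(covariate, order); lin/quad: named coefficient vectors.
linear_predictor <- function(x, terms, intercept, lin, quad) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::as_tibble(as.list(x))
  }
  x <- tibble::as_tibble(x)
  lp <- rep(intercept, max(1L, nrow(x)))
  if (!nrow(terms)) return(lp)
  missing_cov <- setdiff(unique(terms$covariate), names(x))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) named in the model spec but absent from the data: ",
                 paste(missing_cov, collapse = ", ")))
  }
  for (i in seq_len(nrow(terms))) {
    cov <- terms$covariate[i]
    ord <- terms$order[i]
    cf <- if (ord == 1) lin[[cov]] %||% NA_real_ else -(quad[[cov]] %||% NA_real_)
    if (is.na(cf)) {
      abort(paste0("no coefficient supplied for ", cov, " (order ", ord, ")"))
    }
    lp <- lp + cf * x[[cov]]^ord
  }
  lp
}

#' Fecundity as a climate response curve
#'
#' Evaluates the logit-linear/quadratic fecundity predictor
#' `logit(b) = alpha0 + sum_i sum_r alpha_ir * x_i^r + eps_t` and returns the
#' inverse logit. Quadratic coefficients are applied with a negative sign, so
#' a positive magnitude gives a downward parabola with an interior optimum at
#' `x* = alpha_lin / (2 * alpha_quad)`.
#'
#' @param x A data frame with one column per standardized covariate (or a
#'   named numeric vector for a single row).
#' @param params A [demographic_params()] object.
#' @param spec A [model_spec()]; only its `fecundity_terms` are used.
#' @param eps_t Shared annual noise on the logit scale (scalar or one value
#'   per row of `x`).
#' @return Numeric vector of fecundities, strictly in (0, 1).
#' @examples
#' p <- demographic_params(alpha0 = 0.969, alpha_lin = c(nsAT = 1.546),
#'                         alpha_quad = c(nsAT = 0.848))
#' s <- model_spec(fecundity = c(nsAT = 2))
#' xstar <- 1.546 / (2 * 0.848)
#' fecundity_rate(c(nsAT = xstar), p, s) # peak fecundity, ~0.84
#' @export
fecundity_rate <- function(x, params, spec, eps_t = 0) {
  lp <- linear_predictor(x, spec$fecundity_terms, params$alpha0,
                         params$alpha_lin, params$alpha_quad)
  invlogit(lp + eps_t)
}

#' Marine density-dependence coefficient as a climate response
#'
#' Evaluates `logit(eta) = beta0 + sum_i sum_r beta_ir * x_i^r` (no annual
#' noise term). `eta` scales how strongly colony size depresses recruitment
#' through the marine environment; its reciprocal sets the marine carrying
#' capacity via [marine_carrying_capacity()].
#'
#' @inheritParams fecundity_rate
#' @return Numeric vector of `eta` values, strictly in (0, 1).
#' @export
marine_dd <- function(x, params, spec) {
  invlogit(linear_predictor(x, spec$recruitment_terms, params$beta0,
                            params$beta_lin, params$beta_quad))
}

#' Terrestrial density-dependence coefficient from carrying capacity
#'
#' `nu = (alpha_const - logit(re)) / K`: the slope at which recruitment falls
#' to the baseline rate `re` exactly when colony size reaches the terrestrial
#' carrying capacity `K`.
#'
#' @param K Terrestrial carrying capacity (AOS), `> 0` (vectorised).
#' @param params A [demographic_params()] object (uses `alpha_const`, `re`).
#' @return Positive numeric vector `nu` with `nu * K = alpha_const - logit(re)`.
#' @export
terrestrial_dd <- function(K, params) {
  if (any(K <= 0)) abort("`K` must be > 0")
  (params$alpha_const - logit(params$re)) / K
}

#' Density-dependent recruitment rate
#'
#' Computes `logit^-1(alpha_const - max(nu, eta) * P)`: recruitment is practically
#' 1 in an empty colony and decays logistically with colony size under the
#' stronger of the terrestrial (`nu`) and marine (`eta`) density-dependence
#' coefficients. At `P` equal to the binding carrying capacity, recruitment
#' equals `re` exactly.
#'
#' @param P Colony size (AOS), `>= 0` (vectorised).
#' @param nu,eta Terrestrial and marine density-dependence coefficients.
#' @param params A [demographic_params()] object (uses `alpha_const`).
#' @return Recruitment probabilities, strictly in (0, 1).
#' @export
recruitment_rate <- function(P, nu, eta, params) {
  if (any(P < 0)) abort("colony size `P` must be >= 0")
  invlogit(params$alpha_const - pmax(nu, eta) * P)
}

#' Marine carrying capacity implied by the marine density dependence
#'
#' `C = (alpha_const - logit(re)) / eta`; the colony size at which purely
#' marine-regulated recruitment falls to the baseline rate `re`. Unlike the
#' fixed terrestrial `K`, `C` varies with climate through `eta`.
#'
#' @param eta Marine density-dependence coefficient, in (0, 1) (vectorised).
#' @inheritParams terrestrial_dd
#' @return Positive capacities (AOS); `marine_carrying_capacity(terrestrial_dd(K)) == K`.
#' @export
marine_carrying_capacity <- function(eta, params) {
  if (any(eta <= 0)) abort("`eta` must be > 0")
  (params$alpha_const - logit(params$re)) / eta
}

#' Carrying-capacity dominance and regulation regime
#'
#' The signed difference `C - K` between the marine and terrestrial carrying
#' capacities. The smaller capacity binds: a positive difference means the
#' terrestrial capacity is limiting ("terrestrial" regulation), a negative
#' one marine regulation. Ties are labelled terrestrial.
#'
#' @param C Marine carrying capacity (AOS), `> 0` (vectorised).
#' @param K Terrestrial carrying capacity (AOS), `> 0`.
#' @return A tibble with columns `dominance` (`C - K`, AOS) and `regulation`
#'   (`"terrestrial"` or `"marine"`).
#' @export
capacity_dominance <- function(C, K) {
  if (any(C <= 0) || any(K <= 0)) abort("capacities must be > 0")
  d <- C - K
  tibble::tibble(dominance = d,
                 regulation = ifelse(d >= 0, "terrestrial", "marine"))
}

#' Adult survival in the avian-influenza year
#'
#' Returns the adult survival applied in the epizootic year (2022 by
#' default): the measured reduced rate for known affected colonies, the
#' regular adult survival for unaffected ones, and for colonies of unknown
#' status a draw from Uniform(0.455, 0.94) in forward simulation (in
#' inference the same range is the prior of a free parameter).
#'
#' @param status Character vector in `{"affected", "unaffected", "unknown"}`.
#' @param params A [demographic_params()] object.
#' @return Numeric survival probabilities, one per element of `status`.
#' @export
hpai_survival <- function(status, params) {
  ok <- c("affected", "unaffected", "unknown")
  if (any(!status %in% ok)) {
    abort(paste0("unknown HPAI status: ",
                 paste(setdiff(status, ok), collapse = ", "),
                 " (expected affected/unaffected/unknown)"))
  }
  out <- numeric(length(status))
  out[status == "affected"] <- params$hpai_phi_affected
  out[status == "unaffected"] <- params$phi_ad
  n_unk <- sum(status == "unknown")
  if (n_unk) {
    out[status == "unknown"] <- runif(n_unk, params$hpai_phi_affected,
                                      params$hpai_phi_max)
  }
  out
}

#' One annual step of the metapopulation process
#'
#' Advances the colony state one year: adults survive (with the
#' avian-influenza override in the epizootic year), each pair fledges
#' `b_{n,t}` chicks (converted to pair-equivalents), pre-breeder cohorts age
#' with juvenile survival, cohorts reaching the age of first breeding are
#' redistributed across colonies by a conspecific-attraction kernel
#' (`w_m` proportional to `P_m`, the natal colony boosted by the philopatry
#' factor `rho`) and settle subject to the colony-specific density-dependent
#' recruitment rate, evaluated implicitly at the post-settlement colony size
#' (arriving prospectors compete with incumbents and with each other for
#' sites, so the annual map approaches a carrying capacity smoothly rather
#' than overshooting it); failed settlers stay one more year in the oldest
#' pre-breeder class and retry until death. All flows are expected-value
#' (deterministic given `eps_t`); redistribution conserves individuals.
#'
#' @param state A [colony_state()].
#' @param climate A data frame with a `colony_id` column and one column per
#'   covariate, holding the standardized values for `state$year`, rows
#'   matching the colonies of `state` (any order).
#' @param params A [demographic_params()] object; `params$K` must cover the
#'   colonies of `state`.
#' @param spec A [model_spec()].
#' @param eps_t Shared annual fecundity noise (logit scale).
#' @param hpai_status Optional named character vector of colony statuses used
#'   only when `state$year == params$hpai_year`.
#' @param phi_override Optional named numeric of adult survival values that
#'   take precedence this year (used by forecasting to fix the
#'   unknown-status draws).
#' @return The [colony_state()] at `year + 1`, with attributes `rates` (a
#'   tibble of `b`, `eta`, `nu`, `r`, `C` per colony) attached.
#' @export
step_metapopulation <- function(state, climate, params, spec, eps_t = 0,
                                hpai_status = NULL, phi_override = NULL) {
  ids <- names(state$P)
  climate <- tibble::as_tibble(climate)
  if (!"colony_id" %in% names(climate) ||
      !setequal(climate$colony_id, ids) ||
      nrow(climate) != length(ids)) {
    abort("`climate` must hold exactly one row per colony of `state` (column `colony_id`)")
  }
  climate <- climate[match(ids, climate$colony_id), , drop = FALSE]
  if (!all(ids %in% names(params$K))) {
    abort("`params$K` must name every colony in `state`")
  }

  b <- fecundity_rate(climate, params, spec, eps_t)
  eta <- marine_dd(climate, params, spec)
  nu <- terrestrial_dd(params$K[ids], params)
  r <- recruitment_rate(state$P, nu, eta, params)

  # adult survival, with the one-year epizootic shock
  phi <- rep(params$phi_ad, length(ids))
  names(phi) <- ids
  if (!is.null(hpai_status) && state$year == params$hpai_year) {
    phi <- hpai_survival(hpai_status[ids], params)
    names(phi) <- ids
  }
  if (!is.null(phi_override)) {
    phi[names(phi_override)] <- phi_override
  }

  a <- params$a_first
  J <- state$J
  Jnew <- matrix(0, nrow(J), ncol(J), dimnames = dimnames(J))
  # age with juvenile survival; failed retries accumulate in the oldest class
  if (a >= 2) {
    Jnew[, 2:a] <- params$phi_juv * J[, 1:(a - 1), drop = FALSE]
    Jnew[, a] <- Jnew[, a] + params$phi_juv * J[, a]
    eligible <- Jnew[, a]
    Jnew[, a] <- 0
  } else {
    eligible <- params$phi_juv * J[, 1]
    Jnew[, 1] <- 0
  }
  # conspecific-attraction redistribution of the recruitment-eligible pool
  W <- matrix(state$P, length(ids), length(ids), byrow = TRUE) # W[natal, dest] = P_dest
  diag(W) <- params$rho * state$P
  rs <- rowSums(W)
  stay <- rs <= 0
  if (any(stay)) {
    W[stay, ] <- 0
    diag(W)[stay] <- 1
    rs[stay] <- 1
  }
  arrivals <- colSums(W / rs * eligible)
  # implicit within-season settlement: arrivals settle until density
  # dependence (evaluated at the post-settlement colony size) chokes
  # recruitment off, x = phi*P + arrivals * r(x); monotone in x, so the
  # annual map approaches capacity smoothly instead of overshooting it
  dd <- pmax(nu, eta)
  base <- phi * state$P
  Pnew <- base
  for (i in seq_along(ids)) {
    A <- arrivals[i]
    if (A <= 0) next
    lo <- base[i]
    hi <- base[i] + A
    if (params$alpha_const - dd[i] * hi > 36) {
      x <- hi # far below capacity: r(hi) == 1 to double precision
    } else if (params$alpha_const - dd[i] * base[i] < -36) {
      x <- base[i] + A * invlogit(params$alpha_const - dd[i] * base[i])
    } else {
      x <- params$alpha_const / dd[i]
      if (x <= lo || x >= hi) x <- (lo + hi) / 2
      for (it in 1:12) {
        rr <- invlogit(params$alpha_const - dd[i] * x)
        f <- x - base[i] - A * rr
        if (abs(f) < 1e-7 * (1 + A)) break
        if (f > 0) hi <- x else lo <- x
        xn <- x - f / (1 + A * dd[i] * rr * (1 - rr))
        if (!(xn > lo && xn < hi)) xn <- (lo + hi) / 2
        if (abs(xn - x) < 1e-12 * (1 + x)) { x <- xn; break }
        x <- xn
      }
    }
    Pnew[i] <- min(max(x, base[i]), base[i] + A)
  }
  recruits <- Pnew - base
  # new cohort from this year's breeding first (so that with a_first = 1 the
  # failed settlers are added to, not clobbered by, the new cohort)
  Jnew[, 1] <- params$chick_pair * b * state$P
  Jnew[, a] <- Jnew[, a] + pmax(arrivals - recruits, 0)

  out <- colony_state(Pnew, state$year + 1L, params, J = Jnew)
  attr(out, "rates") <- tibble::tibble(
    colony_id = ids, year = state$year, b = b, eta = eta, nu = unname(nu),
    r = unname(r),
    r_realized = unname(ifelse(arrivals > 0, recruits / arrivals, NA_real_)),
    C = marine_carrying_capacity(eta, params)
  )
  out
}

#' Simulate a multi-year metapopulation trajectory (reference implementation)
#'
#' Repeatedly applies [step_metapopulation()] over a span of years and
#' returns a tidy trajectory. This is the plain-R reference path; the fitted
#' model and the forecasting engine use an equivalent compiled simulator, and
#' the two are held to agree to numerical precision in the package tests.
#'
#' @param state0 Initial [colony_state()].
#' @param climate Data frame with columns `colony_id`, `year` and one column
#'   per covariate, covering all simulated years.
#' @param params,spec As in [step_metapopulation()].
#' @param eps Named numeric of annual logit-scale fecundity noise, indexed by
#'   year (`"1960"` etc.); missing years use 0.
#' @param n_years Number of annual steps to take.
#' @param hpai_status,phi_override Passed to [step_metapopulation()] (the
#'   override applies only in `params$hpai_year`).
#' @return A tibble (`colony_id`, `year`, `P`, `J_total`, `b`, `eta`, `nu`,
#'   `r`, `C`) covering years `state0$year .. state0$year + n_years`; the
#'   rate columns are `NA` for the final year (no step taken from it).
#' @export
simulate_metapopulation <- function(state0, climate, params, spec, n_years,
                                    eps = numeric(), hpai_status = NULL,
                                    phi_override = NULL) {
  state <- state0
  rows <- vector("list", n_years + 1)
  rates <- vector("list", n_years)
  for (k in seq_len(n_years)) {
    yr <- state$year
    cl <- dplyr::filter(climate, .data$year == yr)
    e <- if (as.character(yr) %in% names(eps)) eps[[as.character(yr)]] else 0
    po <- if (yr == params$hpai_year) phi_override else NULL
    nxt <- step_metapopulation(state, cl, params, spec, eps_t = e,
                               hpai_status = hpai_status, phi_override = po)
    rows[[k]] <- tibble::tibble(colony_id = names(state$P), year = yr,
                                P = unname(state$P),
                                J_total = unname(rowSums(state$J)))
    rates[[k]] <- attr(nxt, "rates")
    state <- nxt
  }
  rows[[n_years + 1]] <- tibble::tibble(colony_id = names(state$P),
                                        year = state$year,
                                        P = unname(state$P),
                                        J_total = unname(rowSums(state$J)))
  dplyr::bind_rows(rows) |>
    dplyr::left_join(dplyr::bind_rows(rates), by = c("colony_id", "year"))
}
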