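# Scenario forecasting from posterior draws: each retained draw re-simulates
# the fitting window (the process is deterministic given its eps series and
# initial sizes, so the terminal age structure is recovered exactly) and
# continues into the forecast horizon under each scenario's covariates. The
# same future noise and epizootic-survival draws are reused across the two
# scenarios, so scenario contrasts reflect climate, not Monte Carlo noise.

#' Forecast colony trajectories under two climate scenarios
#'
#' @param fit A `metapop_fit` from [run_mcmc()].
#' @param climate Standardized long climate series containing the forecast
#'   scenarios (`"SSP1"`, `"SSP5"`) for all forecast years; defaults to the
#'   series the model was fitted with. Scenario values must be standardized
#'   with the fitting-window constants.
#' @param years Forecast years; default from the year after the fitting
#'   window through 2100.
#' @param n_draws Posterior draws to propagate (subsampled evenly; default
#'   all retained draws up to 200).
#' @param seed Seed for the future process noise and the epizootic-year
#'   survival of unknown-status colonies (paired across scenarios).
#' @param scenarios Scenario names (default `c("SSP1", "SSP5")`).
#' @return An object of class `metapop_forecast`: list with `trajectories`
#'   (tibble: `scenario`, `colony_id`, `year`, `median`, `lower95`,
#'   `upper95`, `C_median`, `dominance`, `regulation`), `totals` (per-year
#'   metapopulation totals: the median of per-draw totals plus, for
#'   reference, the sum of colony medians), and bookkeeping.
#' @export
forecast_scenarios <- function(fit, climate = fit$data$climate,
                               years = NULL, n_draws = 200, seed = 1,
                               scenarios = c("SSP1", "SSP5")) {
  bd <- fit$bd
  if (is.null(years)) years <- (max(bd$years) + 1):2100
  ids <- bd$ids
  n <- length(ids)
  fit_years <- bd$years
  all_years <- c(fit_years, years)
  if (min(years) != max(fit_years) + 1) {
    abort("forecast years must start immediately after the fitting window")
  }
  params <- fit$params
  colonies <- tibble::as_tibble(fit$data$colonies)

  # combined (fitting + scenario) climate, one build per scenario
  scen_bd <- purrr::map(scenarios, function(sc) {
    scen <- dplyr::filter(tibble::as_tibble(climate), .data$scenario == sc,
                          .data$year %in% years)
    if (!nrow(scen) || !all(years %in% scen$year)) {
      abort(paste0("scenario `", sc, "` does not cover every forecast year"))
    }
    hind <- dplyr::filter(tibble::as_tibble(climate),
                          .data$scenario == "hindcast",
                          .data$year %in% fit_years)
    combined <- dplyr::bind_rows(hind,
                                 dplyr::mutate(scen, scenario = "hindcast"))
    empty_census <- tibble::tibble(colony_id = character(), year = integer(),
                                   aos_count = integer())
    build_model_data(list(census = empty_census, fecundity = NULL,
                          climate = combined, colonies = colonies),
                     fit$spec, params, years = all_years)
  })
  names(scen_bd) <- scenarios

  all_nat <- do.call(rbind, fit$nat_chains)
  total <- nrow(all_nat)
  take <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  nd <- length(take)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  Tall <- length(all_years)
  pn_fit <- bd$par_names
  # containers: [draw, colony, year] per scenario
  Parr <- purrr::map(scenarios, ~ array(NA_real_, c(nd, n, Tall)))
  names(Parr) <- scenarios
  Carr <- Parr

  rt <- bd$rt
  for (k in seq_len(nd)) {
    nat <- all_nat[take[k], ]
    sigma_b <- nat[["sigma_b"]]
    eps_future <- rnorm(length(years), 0, sigma_b)
    unk <- ids[colonies$hpai_status == "unknown"]
    phi_unknown <- setNames(runif(length(unk), params$hpai_phi_affected,
                                  params$hpai_phi_max), unk)
    for (sc in scenarios) {
      bd2 <- scen_bd[[sc]]
      nat2 <- setNames(numeric(length(bd2$par_names)), bd2$par_names)
      shared <- intersect(bd2$par_names, pn_fit)
      nat2[shared] <- nat[shared]
      nat2[paste0("eps_", years)] <- eps_future
      hp_names <- grep("^phi[0-9]{4}_", bd2$par_names, value = TRUE)
      if (length(hp_names)) {
        nat2[hp_names] <- phi_unknown[sub("^phi[0-9]{4}_", "", hp_names)]
      }
      sim <- mpc_simulate_cpp(bd2$md, to_sampling_scale(nat2, bd2))
      Parr[[sc]][k, , ] <- sim$P
      # marine carrying capacity from the draw's recruitment coefficients
      lpr <- matrix(nat[["beta0"]], n, Tall)
      if (nrow(rt)) {
        for (j in seq_len(nrow(rt))) {
          cf <- nat[[paste0("beta_", rt$covariate[j],
                            ifelse(rt$order[j] == 2, "2", ""))]]
          if (rt$negative[j]) cf <- -cf
          lpr <- lpr + cf * bd2$md$Zr[[j]]
        }
      }
      eta <- invlogit(lpr)
      Carr[[sc]][k, , ] <- (params$alpha_const - logit(params$re)) / eta
    }
  }

  qmed <- function(a, pr) apply(a, c(2, 3), quantile, probs = pr, names = FALSE)
  Kmed <- apply(all_nat[take, paste0("K_", ids), drop = FALSE], 2, median)
  trajectories <- purrr::map_dfr(scenarios, function(sc) {
    med <- qmed(Parr[[sc]], 0.5); lo <- qmed(Parr[[sc]], 0.025)
    hi <- qmed(Parr[[sc]], 0.975); cm <- qmed(Carr[[sc]], 0.5)
    dom <- cm - matrix(Kmed, n, Tall)
    tibble::tibble(
      scenario = sc,
      colony_id = rep(ids, times = Tall),
      year = rep(all_years, each = n),
      median = as.vector(med), lower95 = as.vector(lo),
      upper95 = as.vector(hi), C_median = as.vector(cm),
      dominance = as.vector(dom),
      regulation = ifelse(as.vector(dom) >= 0, "terrestrial", "marine")
    )
  })
  totals <- purrr::map_dfr(scenarios, function(sc) {
    tot <- apply(Parr[[sc]], c(1, 3), sum) # draw x year
    med_traj <- qmed(Parr[[sc]], 0.5)
    tibble::tibble(
      scenario = sc, year = all_years,
      median = apply(tot, 2, median),
      lower95 = apply(tot, 2, quantile, 0.025, names = FALSE),
      upper95 = apply(tot, 2, quantile, 0.975, names = FALSE),
      sum_of_medians = colSums(med_traj)
    )
  })
  structure(
    list(trajectories = trajectories, totals = totals, years = years,
         fit_years = fit_years, scenarios = scenarios, n_draws = nd,
         seed = seed, colony_ids = ids),
    class = "metapop_forecast"
  )
}

#' @export
print.metapop_forecast <- function(x, ...) {
  cat("<metapop_forecast>", paste(x$scenarios, collapse = " vs "), "|",
      length(x$colony_ids), "colonies |", x$n_draws, "posterior draws |",
      min(x$years), "-", max(x$years), "\n")
  print(sensitivity(x))
  invisible(x)
}

#' Colony climate sensitivity: percent scenario difference in size
#'
#' `100 * (median_SSP5 - median_SSP1) / median_SSP1` at the requested
#' reference years: negative values mean the colony is forecast smaller
#' under the high-emission scenario (disadvantaged), positive values larger
#' (benefitting). Undefined (reported `NA`) where the SSP1 median is zero.
#'
#' @param forecast A `metapop_forecast`.
#' @param years Reference years (default 2030, 2065, 2100).
#' @return Tibble (`colony_id`, `year`, `sensitivity`).
#' @export
sensitivity <- function(forecast, years = c(2030, 2065, 2100)) {
  tr <- forecast$trajectories |>
    dplyr::filter(.data$year %in% years,
                  .data$scenario %in% c("SSP1", "SSP5")) |>
    dplyr::select("scenario", "colony_id", "year", "median") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "median")
  tr |>
    dplyr::mutate(sensitivity = dplyr::if_else(
      .data$SSP1 > 0, 100 * (.data$SSP5 - .data$SSP1) / .data$SSP1,
      NA_real_)) |>
    dplyr::select("colony_id", "year", "sensitivity")
}

#' Classify colony forecast trajectories into qualitative patterns
#'
#' Rule-based labels for the four patterns seen in scenario forecasts:
#' `plateau_same` (scenarios indistinguishable at the horizon and both flat
#' late on), `diverge_decline` (flat under the low-emission scenario,
#' falling from its own peak under the high-emission one),
#' `increase_unbounded` (still growing in the final decades under both) and
#' `decline_both` (ends below half of its early-horizon size under both).
#' All thresholds are exposed as arguments.
#'
#' @param forecast A `metapop_forecast`.
#' @param same_tol Relative end-horizon scenario difference below which
#'   scenarios count as "not differing" (default 0.10).
#' @param slope_tol Absolute late-horizon relative slope (per year) below
#'   which a trajectory counts as plateaued (default 0.005).
#' @param peak_drop High-emission end median below this fraction of its own
#'   peak counts as scenario-driven decline (default 0.9).
#' @param decline_frac End median below this fraction of the reference-year
#'   (2030) median counts as drastic decline (default 0.5).
#' @param late_window Years over which the late-horizon slope is measured
#'   (default 20).
#' @param ref_year Early-horizon reference year for the decline rule.
#' @return Tibble (`colony_id`, `pattern`).
#' @export
classify_trajectory <- function(forecast, same_tol = 0.10, slope_tol = 0.005,
                                peak_drop = 0.9, decline_frac = 0.5,
                                late_window = 20, ref_year = 2030) {
  tr <- dplyr::filter(forecast$trajectories, .data$year >= min(forecast$years))
  end_year <- max(tr$year)
  purrr::map_dfr(unique(tr$colony_id), function(cid) {
    one <- function(sc) {
      d <- dplyr::filter(tr, .data$colony_id == cid, .data$scenario == sc) |>
        dplyr::arrange(.data$year)
      p_end <- d$median[d$year == end_year]
      p_late0 <- d$median[d$year == end_year - late_window]
      slope <- (p_end - p_late0) / max(p_late0, 1e-9) / late_window
      list(end = p_end, slope = slope, peak = max(d$median),
           ref = d$median[d$year == ref_year])
    }
    s1 <- one("SSP1"); s5 <- one("SSP5")
    end_diff <- abs(s5$end - s1$end) / max(s1$end, 1e-9)
    plateau1 <- abs(s1$slope) < slope_tol
    plateau5 <- abs(s5$slope) < slope_tol
    pattern <- if (end_diff < same_tol && plateau1 && plateau5) {
      "plateau_same"
    } else if (plateau1 && s5$end < peak_drop * s5$peak) {
      "diverge_decline"
    } else if (s1$slope > slope_tol && s5$slope > slope_tol) {
      "increase_unbounded"
    } else if (s1$end < decline_frac * s1$ref && s5$end < decline_frac * s5$ref) {
      "decline_both"
    } else if (s1$slope < 0 && s5$slope < 0) {
      "decline_both"
    } else {
      "diverge_decline"
    }
    tibble::tibble(colony_id = cid, pattern = pattern)
  })
}
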