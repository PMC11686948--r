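# broom-style tidiers for fitted and forecast objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted metapopulation model
#'
#' @param x A `metapop_fit`.
#' @param pars Which parameters to keep: `"model"` (coefficients, intercepts
#'   and noise SDs; the default), `"capacity"` (terrestrial capacities),
#'   `"latent"` (initial sizes and annual noise) or `"all"`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior median),
#'   `conf.low`, `conf.high` (95 percent credible interval) and `rhat`.
#' @export
tidy.metapop_fit <- function(x, pars = c("model", "capacity", "latent", "all"),
                             ...) {
  pars <- match.arg(pars)
  s <- x$summary
  keep <- switch(pars,
    model = !grepl("^(eps_|P0_|K_)", s$parameter),
    capacity = grepl("^K_", s$parameter),
    latent = grepl("^(eps_|P0_)", s$parameter),
    all = rep(TRUE, nrow(s))
  )
  s[keep, ] |>
    dplyr::rename(term = "parameter", estimate = "median",
                  conf.low = "lower95", conf.high = "upper95")
}

#' Model-level summary of a fit
#'
#' @param x A `metapop_fit`.
#' @param ... Unused.
#' @return One-row tibble: model id, DIC decomposition, chain settings,
#'   worst R-hat and the convergence flag.
#' @export
glance.metapop_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$id,
    dic = if (is.null(x$dic)) NA_real_ else x$dic$dic,
    dbar = if (is.null(x$dic)) NA_real_ else x$dic$dbar,
    p_d = if (is.null(x$dic)) NA_real_ else x$dic$pd,
    n_chains = x$settings$chains,
    n_draws = length(x$loglik),
    max_rhat = suppressWarnings(
      max(x$summary$rhat[is.finite(x$summary$rhat)], na.rm = TRUE)),
    converged = x$converged
  )
}

#' Tidy a scenario forecast
#'
#' @param x A `metapop_forecast`.
#' @param ... Unused.
#' @return The tidy trajectory tibble (scenario, colony, year, posterior
#'   median and interval of colony size, marine capacity and regulation).
#' @export
tidy.metapop_forecast <- function(x, ...) x$trajectories

#' @rdname tidy.metapop_forecast
#' @export
glance.metapop_forecast <- function(x, ...) {
  sens <- sensitivity(x, years = max(x$years))
  tibble::tibble(
    n_colonies = length(x$colony_ids),
    n_draws = x$n_draws,
    horizon = max(x$years),
    median_sensitivity = median(sens$sensitivity, na.rm = TRUE),
    n_disadvantaged = sum(sens$sensitivity < 0, na.rm = TRUE),
    n_benefitting = sum(sens$sensitivity > 0, na.rm = TRUE)
  )
}
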