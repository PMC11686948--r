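# ggplot2 graphics for fits and forecasts

#' Posterior response curve of a demographic rate against one covariate
#'
#' Draws the posterior median and 95 percent credible band of fecundity (or
#' of the marine carrying capacity) as a function of one standardized
#' covariate, all other covariates held at zero.
#'
#' @param fit A `metapop_fit`.
#' @param covariate Covariate name (e.g. `"nsAT"`).
#' @param rate `"fecundity"` or `"capacity"` (marine carrying capacity
#'   implied by the recruitment response).
#' @param xlim Range of standardized covariate values (default -3..3).
#' @return A ggplot object.
#' @export
plot_response_curve <- function(fit, covariate, rate = c("fecundity", "capacity"),
                                xlim = c(-3, 3)) {
  rate <- match.arg(rate)
  grid <- seq(xlim[1], xlim[2], length.out = 101)
  all_nat <- do.call(rbind, fit$nat_chains)
  tt <- if (rate == "fecundity") fit$bd$ft else fit$bd$rt
  pre <- if (rate == "fecundity") "alpha" else "beta"
  icol <- paste0(pre, "0")
  lp <- matrix(all_nat[, icol], nrow(all_nat), length(grid))
  for (j in seq_len(nrow(tt))) {
    if (tt$covariate[j] != covariate) next
    cf <- all_nat[, paste0(pre, "_", tt$covariate[j],
                           ifelse(tt$order[j] == 2, "2", ""))]
    if (tt$negative[j]) cf <- -cf
    lp <- lp + outer(cf, grid^tt$order[j])
  }
  val <- if (rate == "fecundity") {
    invlogit(lp)
  } else {
    (fit$params$alpha_const - logit(fit$params$re)) / invlogit(lp)
  }
  df <- tibble::tibble(
    x = grid,
    median = apply(val, 2, median),
    lower95 = apply(val, 2, quantile, 0.025, names = FALSE),
    upper95 = apply(val, 2, quantile, 0.975, names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(covariate, " (standardized)"),
                  y = if (rate == "fecundity") "fecundity (chicks per nest)"
                      else "marine carrying capacity (AOS)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_response_curve Trace-style posterior overview of a fit.
#' @param object A `metapop_fit`.
#' @param ... Unused.
#' @export
autoplot.metapop_fit <- function(object, ...) {
  d <- object$draws |>
    dplyr::filter(!grepl("^(eps_|P0_|K_)", .data$parameter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$draw, y = .data$value,
                                  colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain", x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot forecast colony trajectories
#'
#' Posterior median and credible ribbon of colony size per scenario, one
#' facet per colony (sizes drawn in thousands of AOS).
#'
#' @param forecast A `metapop_forecast`.
#' @param colonies Optional subset of colony ids.
#' @return A ggplot object.
#' @export
plot_forecast <- function(forecast, colonies = NULL) {
  d <- forecast$trajectories
  if (!is.null(colonies)) d <- dplyr::filter(d, .data$colony_id %in% colonies)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$median / 1000,
                                  colour = .data$scenario,
                                  fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95 / 1000,
                                      ymax = .data$upper95 / 1000),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = min(forecast$years), linetype = 3) +
    ggplot2::facet_wrap(~colony_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "colony size (AOS / 1000)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_forecast Carrying-capacity dominance trajectories
#'   (marine minus terrestrial capacity; above zero = terrestrial
#'   regulation, below = marine).
#' @export
plot_dominance <- function(forecast, colonies = NULL) {
  d <- forecast$trajectories
  if (!is.null(colonies)) d <- dplyr::filter(d, .data$colony_id %in% colonies)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$dominance / 1000,
                                  colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~colony_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "capacity dominance, C - K (AOS / 1000)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
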