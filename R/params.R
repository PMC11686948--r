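#' Demographic parameters of the metapopulation process model
#'
#' Bundles every parameter of the demographic process: the logit-scale
#' climate response coefficients for fecundity and marine density dependence,
#' survival rates, the recruitment constants, terrestrial carrying capacities
#' and the noise scales of the process and observation models.
#'
#' Quadratic coefficients (`alpha_quad`, `beta_quad`) are stored as
#' non-negative magnitudes; the negative sign of a downward-pointing parabola
#' is applied at evaluation time, so a fitted optimum always exists when the
#' magnitude is positive.
#'
#' @param alpha0 Fecundity intercept on the logit scale.
#' @param alpha_lin Named numeric; linear fecundity coefficients per
#'   covariate (names from [mpc_covariates()]).
#' @param alpha_quad Named numeric; quadratic fecundity coefficient
#'   magnitudes (applied with negative sign), must be `>= 0`.
#' @param beta0 Recruitment density-dependence intercept (logit scale).
#' @param beta_lin,beta_quad Recruitment analogues of the fecundity
#'   coefficients.
#' @param sigma_b Standard deviation of the shared annual fecundity noise
#'   `eps_t` on the logit scale.
#' @param phi_ad Adult annual survival probability, in (0, 1).
#' @param phi_juv Pre-breeder annual survival probability, in (0, 1).
#' @param a_first Age (years) of first breeding attempt; integer `>= 1`.
#' @param re Baseline recruitment rate at equilibrium, in (0, 1). Must be the
#'   same value in the terrestrial and marine capacity formulas.
#' @param alpha_const Recruitment steepness constant (dimensionless); with
#'   the default 100 recruitment is practically 1 in an empty colony.
#' @param K Named numeric; terrestrial carrying capacity per colony, in AOS
#'   (Apparently Occupied Sites), all `> 0`.
#' @param sigma_obs Census observation noise SD on the log scale.
#' @param rho Philopatry factor: the natal colony's weight in the
#'   conspecific-attraction kernel is `rho * P_natal` against `P_m` elsewhere.
#' @param chick_pair Conversion from fledged chicks to prospective AOS
#'   (pair-equivalents); default 0.5, i.e. two fledglings form one
#'   prospective breeding site.
#' @param hpai_phi_affected Adult survival applied in the epizootic year to
#'   colonies of known affected status.
#' @param hpai_phi_max Upper bound of adult survival; also the upper end of
#'   the Uniform prior for unknown-status colonies in the epizootic year.
#' @param hpai_year Calendar year of the one-off avian-influenza survival
#'   shock.
#'
#' @return An object of class `demog_params` (a validated named list).
#' @examples
#' p <- demographic_params(alpha0 = 0.969,
#'                         alpha_lin = c(nsAT = 1.546, prec = 0.139),
#'                         alpha_quad = c(nsAT = 0.848),
#'                         beta0 = -6.619, beta_lin = c(SST = 0.881),
#'                         K = c(A = 60000, B = 2000))
#' terrestrial_dd(p$K, p)
#' @export
demographic_params <- function(alpha0 = 0,
                               alpha_lin = numeric(),
                               alpha_quad = numeric(),
                               beta0 = -6,
                               beta_lin = numeric(),
                               beta_quad = numeric(),
                               sigma_b = 0.3,
                               phi_ad = 0.94,
                               phi_juv = 0.8,
                               a_first = 5L,
                               re = 0.3,
                               alpha_const = 100,
                               K = c(colony_1 = 10000),
                               sigma_obs = 0.1,
                               rho = 3,
                               chick_pair = 0.5,
                               hpai_phi_affected = 0.455,
                               hpai_phi_max = 0.94,
                               hpai_year = 2022L) {
  chk_named <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      abort(paste0("`", what, "` must be a named numeric vector"))
    }
    bad <- setdiff(names(x), mpc_covariates())
    if (length(bad)) {
      abort(paste0("unknown covariate(s) in `", what, "`: ",
                   paste(bad, collapse = ", ")))
    }
    x
  }
  alpha_lin <- chk_named(alpha_lin, "alpha_lin")
  alpha_quad <- chk_named(alpha_quad, "alpha_quad")
  beta_lin <- chk_named(beta_lin, "beta_lin")
  beta_quad <- chk_named(beta_quad, "beta_quad")
  if (any(alpha_quad < 0) || any(beta_quad < 0)) {
    abort("quadratic coefficient magnitudes must be >= 0 (sign applied at evaluation)")
  }
  for (nm in c("phi_ad", "phi_juv", "re")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) {
      abort(paste0("`", nm, "` must be a single value strictly in (0, 1)"))
    }
  }
  if (a_first < 1 || a_first != round(a_first)) abort("`a_first` must be an integer >= 1")
  if (alpha_const <= 0) abort("`alpha_const` must be > 0")
  if (any(K <= 0)) abort("all terrestrial carrying capacities `K` must be > 0")
  if (is.null(names(K))) names(K) <- paste0("colony_", seq_along(K))
  if (sigma_b < 0 || sigma_obs < 0) abort("noise scales must be >= 0")
  if (rho <= 0) abort("`rho` must be > 0")

  structure(
    list(alpha0 = alpha0, alpha_lin = alpha_lin, alpha_quad = alpha_quad,
         beta0 = beta0, beta_lin = beta_lin, beta_quad = beta_quad,
         sigma_b = sigma_b, phi_ad = phi_ad, phi_juv = phi_juv,
         a_first = as.integer(a_first), re = re, alpha_const = alpha_const,
         K = K, sigma_obs = sigma_obs, rho = rho, chick_pair = chick_pair,
         hpai_phi_affected = hpai_phi_affected, hpai_phi_max = hpai_phi_max,
         hpai_year = as.integer(hpai_year)),
    class = "demog_params"
  )
}

#' @export
print.demog_params <- function(x, ...) {
  cat("<demog_params>", length(x$K), "colonies\n")
  cat("  fecundity:  alpha0 =", signif(x$alpha0, 4))
  if (length(x$alpha_lin)) {
    cat(" | linear:", paste0(names(x$alpha_lin), "=", signif(x$alpha_lin, 4),
                             collapse = ", "))
  }
  if (length(x$alpha_quad)) {
    cat(" | quadratic:", paste0(names(x$alpha_quad), "=-", signif(x$alpha_quad, 4),
                                collapse = ", "))
  }
  cat("\n  recruitment: beta0 =", signif(x$beta0, 4))
  if (length(x$beta_lin)) {
    cat(" | linear:", paste0(names(x$beta_lin), "=", signif(x$beta_lin, 4),
                             collapse = ", "))
  }
  cat("\n  survival: phi_ad =", x$phi_ad, " phi_juv =", x$phi_juv,
      " a_first =", x$a_first, "\n")
  cat("  recruitment constants: re =", x$re, " alpha_const =", x$alpha_const,
      " rho =", x$rho, "\n")
  cat("  noise: sigma_b =", x$sigma_b, " sigma_obs =", x$sigma_obs, "\n")
  invisible(x)
}

#' Initial colony state for the metapopulation process
#'
#' @param P Named numeric of breeder abundance (AOS) per colony.
#' @param year Calendar year of the state.
#' @param params A [demographic_params()] object (used for `a_first` and to
#'   seed the pre-breeder pools at their deterministic quasi-equilibrium when
#'   `J` is not supplied).
#' @param J Optional matrix of pre-breeders (colonies x age classes
#'   `1..a_first`). When omitted, each cohort is initialised at
#'   `chick_pair * b0 * P * phi_juv^(a-1)` with `b0` the fecundity implied by
#'   an all-zero climate anomaly.
#' @param b0 Fecundity used to seed the pre-breeder pools; default
#'   `plogis(alpha0)`.
#' @return An object of class `colony_state`: list with `P`, `J`, `year`.
#' @export
colony_state <- function(P, year, params, J = NULL, b0 = NULL) {
  if (is.null(names(P))) abort("`P` must be named by colony")
  if (any(P < 0)) abort("abundances must be >= 0")
  a <- params$a_first
  if (is.null(J)) {
    b0 <- b0 %||% invlogit(params$alpha0)
    J <- outer(params$chick_pair * b0 * P, params$phi_juv^(seq_len(a) - 1))
  }
  J <- as.matrix(J)
  if (nrow(J) != length(P) || ncol(J) != a) {
    abort("`J` must be a (colonies x a_first) matrix")
  }
  if (any(J < 0)) abort("abundances must be >= 0")
  rownames(J) <- names(P)
  structure(list(P = P, J = J, year = as.integer(year)),
            class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  cat("<colony_state> year", x$year, "\n")
  print(tibble::tibble(colony_id = names(x$P), breeders = unname(x$P),
                       pre_breeders = unname(rowSums(x$J))))
  invisible(x)
}
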