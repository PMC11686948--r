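#' Candidate model structure: which covariates enter which demographic rate
#'
#' A model spec names the covariate terms of the fecundity and recruitment
#' logit-linear predictors. A covariate may enter linearly (order 1) or as a
#' downward-pointing parabola (orders 1 + 2); an order-2 term always implies
#' the order-1 term for the same covariate.
#'
#' @param fecundity,recruitment Named integer vectors giving the maximum
#'   polynomial order per covariate, e.g. `c(nsAT = 2, prec = 1)`. Empty for
#'   an intercept-only rate.
#' @return An object of class `model_spec` with tibbles `fecundity_terms` and
#'   `recruitment_terms` (columns `covariate`, `order`) and an `id` string
#'   following the conventional suite naming (`m0.00`, `m1.10`, ...,
#'   `m3.3^251`).
#' @examples
#' model_spec(fecundity = c(nsAT = 2, prec = 1), recruitment = c(SST = 1))
#' @export
model_spec <- function(fecundity = integer(), recruitment = integer()) {
  specs <- list(fecundity = fecundity, recruitment = recruitment)
  terms <- lapply(specs, function(x) {
    if (!length(x)) {
      return(tibble::tibble(covariate = character(), order = integer()))
    }
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("model terms must be a named vector, e.g. c(nsAT = 2)")
    }
    bad <- setdiff(names(x), mpc_covariates())
    if (length(bad)) {
      abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")))
    }
    if (any(!x %in% 1:2)) abort("polynomial order can only be 1 or 2")
    # insertion order is kept: the suite ids list the base covariate first
    purrr::map2_dfr(names(x), x, function(cov, ord) {
      tibble::tibble(covariate = cov, order = seq_len(ord))
    })
  })
  out <- structure(
    list(fecundity_terms = terms$fecundity,
         recruitment_terms = terms$recruitment),
    class = "model_spec"
  )
  out$id <- spec_id(out)
  out
}

# Table-style id: "m<k>.<fec digits><rec digits>", one digit per covariate in
# table order (SST=1, SLM=2, nsAT=3, nsWS=4, prec=5), "^2" marking a
# quadratic, "0" for an empty rate; k counts (rate, covariate) slots.
spec_id <- function(spec) {
  digit <- function(terms) {
    if (!nrow(terms)) return("0")
    terms |>
      dplyr::summarise(order = max(.data$order), .by = "covariate") |>
      dplyr::mutate(d = paste0(match(.data$covariate, mpc_covariates()),
                               ifelse(.data$order == 2, "^2", ""))) |>
      dplyr::pull("d") |>
      paste(collapse = "")
  }
  k <- dplyr::n_distinct(spec$fecundity_terms$covariate) +
    dplyr::n_distinct(spec$recruitment_terms$covariate)
  paste0("m", k, ".", digit(spec$fecundity_terms), digit(spec$recruitment_terms))
}

#' @export
print.model_spec <- function(x, ...) {
  fmt <- function(terms) {
    if (!nrow(terms)) return("intercept only")
    terms |>
      dplyr::summarise(order = max(.data$order), .by = "covariate") |>
      dplyr::mutate(lbl = paste0(.data$covariate,
                                 ifelse(.data$order == 2, " (quadratic)", ""))) |>
      dplyr::pull("lbl") |>
      paste(collapse = " + ")
  }
  cat("<model_spec>", x$id, "\n")
  cat("  fecundity:  ", fmt(x$fecundity_terms), "\n")
  cat("  recruitment:", fmt(x$recruitment_terms), "\n")
  invisible(x)
}

#' Enumerate the candidate model suite
#'
#' Builds the 47-model candidate suite: the null (intercept-only) model, the
#' five single-covariate fecundity and five single-covariate recruitment
#' models, all 25 one-covariate-each pairs, three quadratic extensions of the
#' best pair (nsAT fecundity + SST recruitment), and eight models adding a
#' second fecundity covariate to that pair with nsAT either linear or
#' quadratic.
#'
#' @return A tibble with columns `id`, `spec` (list-column of
#'   [model_spec()] objects), `n_terms`.
#' @examples
#' suite <- enumerate_models()
#' nrow(suite) # 47
#' @export
enumerate_models <- function() {
  covs <- mpc_covariates()
  specs <- list(model_spec())
  for (f in covs) specs <- c(specs, list(model_spec(fecundity = setNames(1L, f))))
  for (r in covs) specs <- c(specs, list(model_spec(recruitment = setNames(1L, r))))
  for (f in covs) {
    for (r in covs) {
      specs <- c(specs, list(model_spec(fecundity = setNames(1L, f),
                                        recruitment = setNames(1L, r))))
    }
  }
  # quadratic extensions of the best single-covariate pair (nsAT b, SST a1)
  specs <- c(specs,
             list(model_spec(fecundity = c(nsAT = 1L), recruitment = c(SST = 2L)),
                  model_spec(fecundity = c(nsAT = 2L), recruitment = c(SST = 1L)),
                  model_spec(fecundity = c(nsAT = 2L), recruitment = c(SST = 2L))))
  # second fecundity covariate, with nsAT linear then quadratic
  second <- setdiff(covs, "nsAT")
  for (ord in 1:2) {
    for (s in second) {
      fec <- setNames(c(ord, 1L), c("nsAT", s))
      specs <- c(specs, list(model_spec(fecundity = fec,
                                        recruitment = c(SST = 1L))))
    }
  }
  tibble::tibble(
    id = purrr::map_chr(specs, "id"),
    spec = specs,
    n_terms = purrr::map_int(
      specs,
      ~ dplyr::n_distinct(.x$fecundity_terms$covariate) +
        dplyr::n_distinct(.x$recruitment_terms$covariate)
    )
  )
}
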