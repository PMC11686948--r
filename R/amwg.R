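#' Adaptive Metropolis-within-Gibbs on an arbitrary log posterior
#'
#' The reference implementation of the sampling scheme used by
#' [run_mcmc()]'s compiled engine: one random-walk update per coordinate per
#' sweep, with each proposal scale adapted in batches towards an acceptance
#' rate of 0.44 (diminishing adaptation). Useful for small custom targets
#' and for validating the engine against closed-form posteriors.
#'
#' @param log_post Function mapping a numeric vector to a log density (up to
#'   a constant); may return `-Inf` outside the support.
#' @param init Numeric starting vector.
#' @param n_iter Total sweeps.
#' @param burn Burn-in sweeps discarded.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param scale0 Initial proposal SD.
#' @param adapt_batch Sweeps per adaptation batch.
#' @return Matrix of retained draws (rows = draws), with column names from
#'   `names(init)`.
#' @examples
#' # standard normal target
#' d <- amwg_sample(function(x) -0.5 * sum(x^2), c(a = 0), 2000, burn = 500)
#' c(mean(d), sd(d))
#' @export
amwg_sample <- function(log_post, init, n_iter, burn = floor(n_iter / 4),
                        thin = 1, scale0 = 0.1, adapt_batch = 50) {
  p <- length(init)
  v <- as.numeric(init)
  lp <- log_post(v)
  if (!is.finite(lp)) abort("initial point has non-finite log posterior")
  lsd <- rep(log(scale0), p)
  acc <- integer(p)
  batch <- 0
  keep_idx <- seq_len(n_iter) > burn & ((seq_len(n_iter) - burn) %% thin == 0)
  out <- matrix(NA_real_, sum(keep_idx), p,
                dimnames = list(NULL, names(init)))
  k <- 0
  for (it in seq_len(n_iter)) {
    for (i in seq_len(p)) {
      cand <- v
      cand[i] <- v[i] + exp(lsd[i]) * rnorm(1)
      lpc <- log_post(cand)
      if (is.finite(lpc) && log(runif(1)) < lpc - lp) {
        v <- cand
        lp <- lpc
        acc[i] <- acc[i] + 1L
      }
    }
    if (it %% adapt_batch == 0) {
      batch <- batch + 1
      delta <- min(0.05, 1 / sqrt(batch))
      lsd <- lsd + ifelse(acc / adapt_batch > 0.44, delta, -delta)
      acc[] <- 0L
    }
    if (keep_idx[it]) {
      k <- k + 1
      out[k, ] <- v
    }
  }
  out
}
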