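#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-based ESS using Geyer's initial positive/monotone
#' sequence estimator on pairwise sums of autocorrelations. The estimate is
#' capped at the chain length (an antithetic chain can nominally exceed it),
#' and a constant chain is reported as 0 with a warning. Chains with
#' ESS below 200 trigger a convergence warning in [fit_model()].
#'
#' @param chain Numeric vector of at least 10 samples.
#' @return The effective sample size (numeric scalar).
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 10L) stop("effective_sample_size needs at least 10 samples", call. = FALSE)
  if (sd(chain) == 0) {
    warning("constant chain: effective sample size is 0")
    return(0)
  }
  lag_max <- min(n - 1L, max(200L, floor(10 * sqrt(n))))
  rho <- drop(acf(chain, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)
  # Geyer: Gamma_m = rho_{2m} + rho_{2m+1}; keep while positive, force monotone
  m_max <- floor((length(rho) - 1L) / 2)
  gam <- rho[2 * seq_len(m_max) - 1] + rho[2 * seq_len(m_max)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1L] - 1L)]
  if (length(gam) > 1L) gam <- cummin(gam)
  tau <- max(-1 + 2 * sum(gam), 1e-8)
  ess <- n / tau
  if (ess > n) {
    warning("estimated ESS exceeds chain length (antithetic chain); capping at length")
    ess <- n
  }
  ess
}
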