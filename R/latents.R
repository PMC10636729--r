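#' One Metropolis update of binary-trait latent liabilities
#'
#' The latent liability of a Bernoulli-logit trait has conditional density
#' proportional to `N(liability | predictor, resid_sd^2) *
#' Bernoulli(outcome | plogis(liability))`. This performs one random-walk
#' Metropolis update per site (vectorised), which satisfies detailed balance
#' with respect to that conditional.
#'
#' @param current Numeric vector of current liabilities.
#' @param predictors Conditional mean of each liability (linear predictor,
#'   plus any shift induced by residual covariance with other traits).
#' @param outcomes 0/1 outcomes; `NA` outcomes get a direct draw from the
#'   normal prior part (used when a unit's binary trait is unobserved).
#' @param tuning Proposal standard deviation, scalar or per-site vector.
#' @param resid_sd Residual standard deviation of the liability (1 by
#'   definition on the marginal scale; smaller when conditioning on
#'   correlated residuals of other traits).
#'
#' @return Updated liabilities, with the per-site acceptance indicator in
#'   attribute `"accepted"`.
#' @export
update_binary_latents <- function(current, predictors, outcomes,
                                  tuning = 1.5, resid_sd = 1) {
  n <- length(current)
  stopifnot(length(predictors) %in% c(1L, n))
  if (!all(outcomes %in% c(0, 1) | is.na(outcomes))) {
    stop("outcomes must be 0/1 (or NA for unobserved)", call. = FALSE)
  }
  predictors <- rep_len(predictors, n)
  resid_sd <- rep_len(resid_sd, n)
  tuning <- rep_len(tuning, n)

  prop <- current + tuning * rnorm(n)
  # log target: normal part + Bernoulli-logit part
  log_ratio <- dnorm(prop, predictors, resid_sd, log = TRUE) -
    dnorm(current, predictors, resid_sd, log = TRUE)
  obs <- !is.na(outcomes)
  if (any(obs)) {
    y <- outcomes[obs]
    log_ratio[obs] <- log_ratio[obs] +
      y * (plogis(prop[obs], log.p = TRUE) - plogis(current[obs], log.p = TRUE)) +
      (1 - y) * (plogis(-prop[obs], log.p = TRUE) - plogis(-current[obs], log.p = TRUE))
  }
  accept <- log(runif(n)) < log_ratio
  out <- ifelse(accept, prop, current)
  if (any(!obs)) {
    # unobserved: conditional is the normal part alone; draw exactly
    out[!obs] <- rnorm(sum(!obs), predictors[!obs], resid_sd[!obs])
    accept[!obs] <- TRUE
  }
  attr(out, "accepted") <- accept
  out
}
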