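#' Posterior mode of an MCMC sample
#'
#' Mode of a Gaussian kernel density estimate over the samples (Silverman's
#' rule-of-thumb bandwidth, `stats::bw.nrd0`), evaluated on a 2048-point
#' grid spanning the sample range. Degenerate (constant) samples return the
#' constant.
#'
#' @param samples Numeric vector of at least 50 posterior draws.
#' @return The estimated mode (numeric scalar, inside the sample range).
#' @export
posterior_mode <- function(samples) {
  check_samples(samples)
  if (diff(range(samples)) == 0) return(samples[1])
  d <- density(samples, bw = "nrd0", n = 2048,
               from = min(samples), to = max(samples))
  i <- which.max(d$y)
  # refine around the peak at the same bandwidth to remove grid quantisation
  lo <- d$x[max(i - 2L, 1L)]
  hi <- d$x[min(i + 2L, length(d$x))]
  d2 <- density(samples, bw = d$bw, n = 512, from = lo, to = hi)
  d2$x[which.max(d2$y)]
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(prob * N)` of the
#' sorted samples.
#'
#' @param samples Numeric vector of at least 50 posterior draws.
#' @param prob Target probability mass, in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  check_samples(samples)
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(low = x[i], high = x[i + m])
}

#' MCMC sign probability (pMCMC)
#'
#' Two-sided tail probability that a parameter's sign differs from its
#' dominant sign: `2 * min(fraction > 0, fraction < 0)`, floored at `1/N`
#' (a finite chain can never certify exactly zero) and capped at 1.
#'
#' @param samples Numeric vector of at least 50 posterior draws.
#' @return A probability in (0, 1].
#' @export
pmcmc <- function(samples) {
  check_samples(samples)
  n <- length(samples)
  p <- 2 * min(mean(samples > 0), mean(samples < 0))
  min(max(p, 1 / n), 1)
}

check_samples <- function(samples) {
  if (length(samples) < 50L) {
    stop("at least 50 posterior samples are required", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  invisible(samples)
}

summarize_ratio <- function(samples, prob = 0.95) {
  h <- hpd_interval(samples, prob)
  tibble::tibble(posterior_mode = posterior_mode(samples),
                 hpd_low = h[[1]], hpd_high = h[[2]])
}

#' Repeatability decomposition of a fitted trait
#'
#' Computes, per retained posterior sample, the repeatability ratios for a
#' trait and summarises each with the posterior mode and 95% HPD interval
#' (ratios are always formed sample-by-sample, never from summarised
#' components):
#' \itemize{
#'   \item maternal repeatability: `var_Mother / total`
#'   \item individual repeatability (traits with an individual-level term):
#'     `var_Offspring / total`
#'   \item residual proportion: `var_Residual / total`
#'   \item total repeatability: `(var_Mother + var_Offspring) / total`
#'   \item maternal proportion of total repeatability:
#'     `var_Mother / (var_Mother + var_Offspring)`
#' }
#' where `total` is the sum of all the trait's variance components present
#' in the model.
#'
#' @param samples An `mt_fit`, a wide samples matrix with the standard
#'   parameter names, or a long tidy tibble.
#' @param trait Trait name.
#' @param prob HPD mass.
#' @return A `variance_decomposition` tibble: one row per quantity with
#'   columns `quantity`, `posterior_mode`, `hpd_low`, `hpd_high`, plus
#'   attribute `"draws"` holding the per-sample ratio draws.
#' @export
decompose_variance <- function(samples, trait, prob = 0.95) {
  S <- as_sample_matrix(samples)
  gname <- sprintf("G.motherCov[%s,%s]", trait, trait)
  oname <- sprintf("G.offspringVar[%s]", trait)
  rname <- sprintf("R.resid[%s,%s]", trait, trait)
  if (!gname %in% colnames(S)) {
    stop(sprintf("missing mother-level variance component '%s'", gname), call. = FALSE)
  }
  if (!rname %in% colnames(S)) {
    stop(sprintf("missing residual variance component '%s'", rname), call. = FALSE)
  }
  vm <- S[, gname]
  vr <- S[, rname]
  vo <- if (oname %in% colnames(S)) S[, oname] else NULL
  total <- vm + vr + (vo %||% 0)

  draws <- list(maternal_repeatability = vm / total,
                residual_proportion = vr / total)
  if (!is.null(vo)) {
    draws$individual_repeatability <- vo / total
    draws$total_repeatability <- (vm + vo) / total
    draws$maternal_proportion_of_total <- vm / (vm + vo)
  }
  out <- dplyr::bind_rows(lapply(names(draws), function(q) {
    dplyr::mutate(summarize_ratio(draws[[q]], prob), quantity = q, .before = 1)
  }))
  out <- dplyr::mutate(out, trait = trait, .before = 1)
  attr(out, "draws") <- draws
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' Upper-limit heritability from the mother-offspring covariance
#'
#' Per posterior sample, twice the mother-level covariance between the
#' offspring and maternal expressions of a trait divided by the mother-level
#' variance of the maternal trait (twice the mother-offspring regression
#' slope). Values above 1 are reported as-is: they cannot arise from
#' narrow-sense genetic heritability alone and indicate inflation by shared
#' maternal-environment effects.
#'
#' @param samples An `mt_fit` or samples matrix/tibble.
#' @param offspring_trait,mother_trait Trait names forming the
#'   mother-offspring pair (defaults: subadult and adult-female FID).
#' @param prob HPD mass.
#' @return A one-row tibble `posterior_mode`, `hpd_low`, `hpd_high`, `n_excluded`
#'   with the per-sample draws in attribute `"draws"`. Samples with
#'   non-positive maternal variance are excluded with a warning.
#' @export
upper_limit_h2 <- function(samples, offspring_trait = "subadult_fid",
                           mother_trait = "adult_female_fid", prob = 0.95) {
  S <- as_sample_matrix(samples)
  cn1 <- sprintf("G.motherCov[%s,%s]", offspring_trait, mother_trait)
  cn2 <- sprintf("G.motherCov[%s,%s]", mother_trait, offspring_trait)
  cname <- if (cn1 %in% colnames(S)) cn1 else cn2
  vname <- sprintf("G.motherCov[%s,%s]", mother_trait, mother_trait)
  if (!cname %in% colnames(S) || !vname %in% colnames(S)) {
    stop("samples lack the mother-level covariance or maternal-trait variance",
         call. = FALSE)
  }
  covv <- S[, cname]
  varv <- S[, vname]
  bad <- varv <= 0
  if (any(bad)) {
    warning(sprintf("%d samples with non-positive maternal variance excluded", sum(bad)))
  }
  h2 <- 2 * covv[!bad] / varv[!bad]
  out <- dplyr::mutate(summarize_ratio(h2, prob), n_excluded = sum(bad))
  attr(out, "draws") <- h2
  out
}

#' Fixed-effect posterior summary
#'
#' Posterior mean, HPD interval and pMCMC for every fixed-effect
#' coefficient of a fit.
#'
#' @param fit An `mt_fit`.
#' @param prob HPD mass.
#' @return A tibble with columns `trait`, `term`, `posterior_mean`,
#'   `hpd_low`, `hpd_high`, `pMCMC`.
#' @export
fixed_effect_summary <- function(fit, prob = 0.95) {
  S <- as_sample_matrix(fit)
  cols <- grep("^B\\.fixed\\[", colnames(S), value = TRUE)
  dplyr::bind_rows(lapply(cols, function(cn) {
    inner <- sub("^B\\.fixed\\[(.*)\\]$", "\\1", cn)
    trait <- sub(":.*$", "", inner)
    term <- sub("^[^:]*:", "", inner)
    h <- hpd_interval(S[, cn], prob)
    tibble::tibble(trait = trait, term = term,
                   posterior_mean = mean(S[, cn]),
                   hpd_low = h[[1]], hpd_high = h[[2]],
                   pMCMC = pmcmc(S[, cn]))
  }))
}

#' Mother-level and residual covariance summaries
#'
#' Posterior mode and HPD interval for every (co)variance parameter of a
#' fit (parameters that are structurally fixed, such as masked residual
#' covariances and the unit binary residual variance, appear with
#' zero-width intervals).
#'
#' @param fit An `mt_fit`.
#' @param prob HPD mass.
#' @return A tibble `parameter_name`, `posterior_mode`, `hpd_low`,
#'   `hpd_high`, `pMCMC`.
#' @export
covariance_summary <- function(fit, prob = 0.95) {
  S <- as_sample_matrix(fit)
  cols <- grep("^(G\\.|R\\.)", colnames(S), value = TRUE)
  dplyr::bind_rows(lapply(cols, function(cn) {
    x <- S[, cn]
    h <- hpd_interval(x, prob)
    tibble::tibble(parameter_name = cn,
                   posterior_mode = posterior_mode(x),
                   hpd_low = h[[1]], hpd_high = h[[2]],
                   pMCMC = pmcmc(x))
  }))
}
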