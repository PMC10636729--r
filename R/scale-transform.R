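#' Latent-scale repeatability of a binary trait
#'
#' The intraclass correlation on the latent liability scale:
#' `var_mother / (var_mother + var_residual)`, where the residual liability
#' variance is fixed at 1 for a Bernoulli-logit trait.
#'
#' @param var_mother Mother-level latent variance (>= 0).
#' @param var_residual Residual latent variance (> 0; 1 for binary traits).
#' @return The repeatability ratio in \[0, 1\].
#' @examples
#' latent_repeatability(1.54, 1)
#' @export
latent_repeatability <- function(var_mother, var_residual = 1) {
  if (any(var_mother < 0) || any(var_residual <= 0)) {
    stop("var_mother must be >= 0 and var_residual > 0", call. = FALSE)
  }
  var_mother / (var_mother + var_residual)
}

gauss_hermite_normal <- function(order, sd) {
  gh <- pracma::gaussHermite(order)
  list(x = sqrt(2) * sd * gh$x, w = gh$w / sqrt(pi))
}

#' Data-scale variance components of a Bernoulli-logit trait
#'
#' Converts latent-scale variance components of a binary trait to the
#' observed 0/1 data scale by Gauss-Hermite quadrature, splitting the total
#' phenotypic variance `p(1-p)` into a mother-level part, a residual
#' (overdispersion) part, and the irreducible binomial sampling variance
#' `E[p(1-p)]`.
#'
#' With `p(l) = plogis(l)`, `m ~ N(0, var_mother)`, `e ~ N(0, var_residual)`
#' and the latent means `mu_j` (per-observation linear predictors, averaged
#' with equal weight):
#' \itemize{
#'   \item `expected_phenotype` = `E[p(mu + m + e)]`
#'   \item `var_mother_data` = `Var_m(E[p | m])`
#'   \item `var_binomial` = `E[p(1-p)]`
#'   \item `var_residual_data` = `E_m(Var(p | m))` (everything not
#'     attributable to mothers or to Bernoulli sampling)
#' }
#' These sum exactly to `expected_phenotype * (1 - expected_phenotype)`.
#' The data-scale maternal repeatability is `var_mother_data` over that
#' total — the fully data-scale ratio, with the binomial sampling variance
#' in the denominator.
#'
#' @param var_mother Mother-level latent variance.
#' @param var_residual Residual latent variance (1 for binary traits).
#' @param latent_means Numeric vector of per-observation linear predictors
#'   (or a single intercept).
#' @param quadrature_order Gauss-Hermite order per dimension (>= 21).
#'
#' @return A list of class `data_scale_components` with the four components,
#'   `total` and `maternal_repeatability_data`.
#' @examples
#' data_scale_components(1.54, 1, latent_means = 0.97)
#' @export
data_scale_components <- function(var_mother, var_residual = 1, latent_means = 0,
                                  quadrature_order = 41) {
  if (quadrature_order < 21) stop("quadrature_order must be >= 21", call. = FALSE)
  if (any(!is.finite(latent_means))) stop("latent means must be finite", call. = FALSE)
  if (var_mother < 0 || var_residual < 0) stop("variances must be >= 0", call. = FALSE)

  qm <- gauss_hermite_normal(quadrature_order, sqrt(var_mother))
  qe <- gauss_hermite_normal(quadrature_order, sqrt(var_residual))
  J <- length(latent_means)

  # l[j, e, m] grid of liabilities; collapse over (j, e) for per-m moments
  l <- outer(outer(latent_means, qe$x, `+`), qm$x, `+`)
  p <- plogis(l)
  w_je <- rep(qe$w, each = J) / J                       # weights over (j, e)
  pm <- apply(p, 3, function(s) sum(w_je * s))          # q(m) = E[p | m]
  pm2 <- apply(p^2, 3, function(s) sum(w_je * s))       # E[p^2 | m]
  pq <- apply(p * (1 - p), 3, function(s) sum(w_je * s))

  p_bar <- sum(qm$w * pm)
  e_p2 <- sum(qm$w * pm2)
  var_binomial <- sum(qm$w * pq)
  var_mother_data <- sum(qm$w * pm^2) - p_bar^2
  var_residual_data <- e_p2 - sum(qm$w * pm^2)
  total <- p_bar * (1 - p_bar)

  structure(list(
    expected_phenotype = p_bar,
    var_mother_data = max(var_mother_data, 0),
    var_residual_data = max(var_residual_data, 0),
    var_binomial = var_binomial,
    total = total,
    maternal_repeatability_data = max(var_mother_data, 0) / total,
    var_mother_latent = var_mother,
    var_residual_latent = var_residual,
    quadrature_order = quadrature_order
  ), class = "data_scale_components")
}

#' @export
print.data_scale_components <- function(x, ...) {
  cat(sprintf("Data-scale components (latent var_mother = %.3g, var_residual = %.3g)\n",
              x$var_mother_latent, x$var_residual_latent))
  cat(sprintf("  expected phenotype:     %.4f\n", x$expected_phenotype))
  cat(sprintf("  mother-level variance:  %.5f\n", x$var_mother_data))
  cat(sprintf("  residual variance:      %.5f\n", x$var_residual_data))
  cat(sprintf("  binomial sampling:      %.5f\n", x$var_binomial))
  cat(sprintf("  maternal repeatability: %.4f (latent-scale %.4f)\n",
              x$maternal_repeatability_data,
              latent_repeatability(x$var_mother_latent, x$var_residual_latent)))
  invisible(x)
}

#' Monte Carlo oracle for the data-scale components
#'
#' Brute-force estimator of the same quantities as
#' [data_scale_components()], by simulating mother effects, residuals and
#' Bernoulli outcomes. Mother effects are drawn in `n_groups` groups with
#' `n_draws / n_groups` inner draws of `(mu, e)` each; the between-group
#' variance of the group means is corrected for inner sampling noise
#' (one-way ANOVA estimator). Standard errors are obtained by bootstrap over
#' mother groups.
#'
#' @inheritParams data_scale_components
#' @param n_draws Total number of `(mu, m, e)` draws (>= 1e5).
#' @param n_groups Number of distinct mother-effect draws.
#' @param n_boot Bootstrap resamples for the standard errors.
#' @param seed Optional RNG seed.
#'
#' @return A list with elements `estimate` (named vector), `se` (named
#'   vector of Monte Carlo standard errors), `var_outcome` (empirical
#'   variance of the simulated 0/1 outcomes) and `n_draws`.
#' @export
mc_oracle_data_scale <- function(var_mother, var_residual = 1, latent_means = 0,
                                 n_draws = 1e6, n_groups = 2000, n_boot = 200,
                                 seed = NULL) {
  if (n_draws < 1e5) stop("n_draws must be >= 1e5", call. = FALSE)
  J <- max(2L, floor(n_draws / n_groups))
  K <- as.integer(n_groups)
  with_seed(seed, {
    m <- rnorm(K, 0, sqrt(var_mother))
    mu <- matrix(sample(latent_means, K * J, replace = TRUE), K, J)
    e <- matrix(rnorm(K * J, 0, sqrt(var_residual)), K, J)
    p <- plogis(mu + m + e)
    y <- matrix(rbinom(K * J, 1, p), K, J)

    qk <- rowMeans(p)                 # per-group E[p | m] estimate
    s2k <- apply(p, 1, var)           # per-group within variance
    pqk <- rowMeans(p * (1 - p))
    p2k <- rowMeans(p^2)

    comp <- function(ix) {
      p_bar <- mean(qk[ix])
      vm <- stats::var(qk[ix]) - mean(s2k[ix]) / J
      vr <- mean(s2k[ix])
      vb <- mean(pqk[ix])
      total <- p_bar * (1 - p_bar)
      c(expected_phenotype = p_bar,
        var_mother_data = vm,
        var_residual_data = vr,
        var_binomial = vb,
        total = total,
        maternal_repeatability_data = vm / total)
    }
    est <- comp(seq_len(K))
    boot <- replicate(n_boot, comp(sample.int(K, K, replace = TRUE)))
    se <- apply(boot, 1, sd)
    list(estimate = est, se = se, var_outcome = stats::var(as.numeric(y)),
         n_draws = K * J, n_groups = K)
  })
}

#' Posterior of data-scale components for a fitted binary trait
#'
#' Applies [data_scale_components()] to each retained posterior sample of a
#' fitted model: the mother-level latent variance is the trait's diagonal
#' element of the mother covariance matrix, the residual latent variance is
#' 1, and the latent means are the per-observation fixed-effect linear
#' predictors implied by that sample's coefficients.
#'
#' @param fit An `mt_fit` from [fit_model()] containing a binary trait.
#' @param table The observation table the model was fitted to.
#' @param trait Name of the binary trait (default: the model's only
#'   binary trait).
#' @param quadrature_order Gauss-Hermite order passed through.
#'
#' @return A tibble with one row per retained sample: `iteration`,
#'   `var_mother_latent`, `repeatability_latent`, `expected_phenotype`,
#'   `var_mother_data`, `var_residual_data`, `var_binomial`,
#'   `repeatability_data`.
#' @export
data_scale_posterior <- function(fit, table, trait = NULL, quadrature_order = 31) {
  stopifnot(inherits(fit, "mt_fit"))
  binary <- names(fit$spec$traits)[vapply(fit$spec$traits, function(t)
    t$family == "binary_logit", logical(1))]
  trait <- trait %||% binary[1]
  if (is.na(trait) || !trait %in% binary) {
    stop("no binary trait available for data-scale conversion", call. = FALSE)
  }
  ts <- fit$spec$traits[[trait]]
  df <- as.data.frame(table)
  if (!is.null(df$gps_east_m) && is.null(df$gps_east_km)) {
    df$gps_east_km <- df$gps_east_m / 1000
  }
  df <- df[df$trait == trait, , drop = FALSE]
  for (cv in ts$fixed_effects) df[[cv]] <- as_model_term(df[[cv]], cv)
  X <- design_matrix(df, ts)
  bnames <- sprintf("B.fixed[%s:%s]", trait, colnames(X))
  gname <- sprintf("G.motherCov[%s,%s]", trait, trait)
  S <- fit$samples
  missing <- setdiff(c(bnames, gname), colnames(S))
  if (length(missing)) {
    stop("fit lacks required parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(S)), function(i) {
    mu <- drop(X %*% S[i, bnames])
    vm <- S[i, gname]
    dc <- data_scale_components(vm, 1, latent_means = mu,
                                quadrature_order = quadrature_order)
    tibble::tibble(
      iteration = fit$iterations[i],
      var_mother_latent = vm,
      repeatability_latent = latent_repeatability(vm, 1),
      expected_phenotype = dc$expected_phenotype,
      var_mother_data = dc$var_mother_data,
      var_residual_data = dc$var_residual_data,
      var_binomial = dc$var_binomial,
      repeatability_data = dc$maternal_repeatability_data
    )
  })
  dplyr::bind_rows(rows)
}
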