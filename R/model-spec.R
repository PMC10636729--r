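#' Declare a single response trait for the multi-trait mixed model
#'
#' @param name Trait name as it appears in the observation table's `trait`
#'   column.
#' @param family `"gaussian"` or `"binary_logit"`. Binary traits are modelled
#'   through a latent logit liability whose residual variance is fixed at 1
#'   (a Bernoulli outcome cannot identify a residual scale).
#' @param fixed_effects Character vector of fixed-effect terms; each must
#'   name a column of the observation table (or a derived column such as
#'   `gps_east_km`). An intercept is always included.
#' @param random Random terms for this trait: any subset of
#'   `c("mother", "individual")`. `"mother"` contributes a trait-specific
#'   element of the shared mother-level effect vector (unstructured
#'   covariance across traits); `"individual"` adds an independent scalar
#'   effect per individual (repeated-measures traits only).
#' @param resid_fixed Optional constant at which this trait's residual
#'   variance is held (always 1 for `binary_logit`).
#'
#' @return A `trait_spec` list.
#' @seealso [model_spec()], [fit_model()]
#' @export
trait_spec <- function(name,
                       family = c("gaussian", "binary_logit"),
                       fixed_effects = character(),
                       random = "mother",
                       resid_fixed = NULL) {
  family <- match.arg(family)
  random <- as.character(random)
  if (length(random) && !all(random %in% c("mother", "individual"))) {
    stop("random terms must be a subset of c('mother', 'individual')", call. = FALSE)
  }
  if (family == "binary_logit") resid_fixed <- 1
  structure(list(name = name, family = family,
                 fixed_effects = as.character(fixed_effects),
                 random = random, resid_fixed = resid_fixed),
            class = "trait_spec")
}

#' Declare a multi-trait Bayesian mixed model
#'
#' Combines per-trait declarations with the residual covariance structure
#' and the inverse-Wishart prior. The mother-level covariance matrix is
#' always unstructured across every trait carrying a `"mother"` random term.
#' Residual (co)variances are free within each *residual group* and fixed to
#' exactly zero across groups: traits measured on disjoint observational
#' units (for example offspring traits versus adult-female FID) must sit in
#' different groups, mirroring the impossibility of estimating a residual
#' covariance between them.
#'
#' @param traits List of [trait_spec()] objects.
#' @param resid_groups List of character vectors partitioning (a subset of)
#'   the trait names; traits in the same vector share unit-level residual
#'   vectors with free covariance. Traits not mentioned form singleton
#'   groups. Multi-trait groups require at most one observation per
#'   individual per trait (each individual is the observational unit).
#' @param prior Optional prior overrides: a list with elements `G`
#'   (`list(V, nu)` for the mother-level block), `R` (a list per residual
#'   group), and `v` (`list(V, nu)` for each individual-level variance).
#'   Defaults are weakly informative: scale matrix `V = I`, degrees of
#'   freedom `nu = dim + 0.002` per block.
#'
#' @return A `model_spec` object.
#' @export
model_spec <- function(traits, resid_groups = NULL, prior = NULL) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(all(vapply(traits, inherits, logical(1), "trait_spec")))
  trait_names <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(trait_names)) stop("duplicate trait names", call. = FALSE)
  names(traits) <- trait_names

  resid_groups <- resid_groups %||% list()
  grouped <- unlist(resid_groups)
  if (anyDuplicated(grouped)) stop("a trait may appear in only one residual group", call. = FALSE)
  if (!all(grouped %in% trait_names)) {
    stop("residual groups mention unknown traits: ",
         paste(setdiff(grouped, trait_names), collapse = ", "), call. = FALSE)
  }
  singletons <- setdiff(trait_names, grouped)
  groups <- c(resid_groups, as.list(singletons))
  # keep deterministic order: by first trait's position in `traits`
  ord <- order(vapply(groups, function(g) match(g[[1]], trait_names), integer(1)))
  groups <- groups[ord]

  for (g in groups) {
    if (length(g) > 1L) {
      for (tn in g) {
        if ("individual" %in% traits[[tn]]$random) {
          stop("individual random terms are only supported for traits in singleton residual groups",
               call. = FALSE)
        }
      }
    }
  }

  spec <- structure(list(traits = traits, resid_groups = groups, prior = prior),
                    class = "model_spec")
  spec$prior <- default_prior(spec, prior)
  spec
}

mother_traits <- function(spec) {
  names(spec$traits)[vapply(spec$traits, function(t) "mother" %in% t$random, logical(1))]
}

individual_traits <- function(spec) {
  names(spec$traits)[vapply(spec$traits, function(t) "individual" %in% t$random, logical(1))]
}

default_prior <- function(spec, prior = NULL) {
  tm <- mother_traits(spec)
  pG <- length(tm)
  out <- list()
  if (pG > 0) {
    out$G <- list(V = diag(pG), nu = pG + 0.002)
  }
  out$R <- lapply(spec$resid_groups, function(g) {
    p <- length(g)
    list(V = diag(p), nu = p + 0.002)
  })
  names(out$R) <- vapply(spec$resid_groups, paste, character(1), collapse = "+")
  out$v <- list(V = 1, nu = 1.002)
  utils::modifyList(out, prior %||% list())
}

#' Residual fixed-to-zero mask implied by a model specification
#'
#' @param spec A [model_spec()].
#' @return A symmetric logical trait-by-trait matrix, `TRUE` where the
#'   residual (co)variance is fixed to exactly zero (all cross-group
#'   elements); the diagonal is never masked.
#' @export
resid_zero_mask <- function(spec) {
  tn <- names(spec$traits)
  grp <- integer(length(tn))
  names(grp) <- tn
  for (i in seq_along(spec$resid_groups)) grp[spec$resid_groups[[i]]] <- i
  mask <- outer(grp, grp, `!=`)
  dimnames(mask) <- list(tn, tn)
  mask
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Multi-trait mixed model specification\n")
  for (t in x$traits) {
    cat(sprintf("  %s (%s): ~ %s | random: %s%s\n", t$name, t$family,
                if (length(t$fixed_effects)) paste(t$fixed_effects, collapse = " + ") else "1",
                if (length(t$random)) paste(t$random, collapse = ", ") else "none",
                if (!is.null(t$resid_fixed)) sprintf(" | resid fixed at %g", t$resid_fixed) else ""))
  }
  cat("  residual groups:",
      paste(vapply(x$resid_groups, paste, character(1), collapse = "+"), collapse = " | "), "\n")
  invisible(x)
}

#' MCMC run settings
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before retention (must be
#'   `< n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed governing every draw in the fit.
#' @param proposal_sd Initial random-walk proposal standard deviation for
#'   binary-trait latent liability updates.
#' @param adapt Adapt the liability proposal scales during burn-in only
#'   (adaptation is frozen afterwards so detailed balance holds over the
#'   retained chain).
#'
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 20000, burn_in = 5000, thin = 10, seed = 1L,
                        proposal_sd = 1.5, adapt = TRUE) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), proposal_sd = proposal_sd,
                 adapt = isTRUE(adapt)),
            class = "mcmc_config")
}
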