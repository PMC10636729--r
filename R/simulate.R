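#' Configure a synthetic mother-offspring behaviour dataset
#'
#' Builds the full parameter set for [simulate_dataset()]: the hierarchical
#' design (mothers, offspring per mother, repeated flight-initiation-distance
#' trials), the generating variance components at each level, fixed-effect
#' coefficients, and covariate distributions. Defaults emulate a wild
#' kangaroo-type study population: roughly a hundred mothers with 1-3
#' offspring each, a 0-1 pouch-young movement score built from 8 binary
#' handling stages, repeated FID trials on subadults (mean 4.6 per
#' individual) and on adult females (mean 5.6), and a binary
#' survival-to-weaning outcome with roughly two-thirds survival.
#'
#' Traits are generated as:
#' \describe{
#'   \item{py_movement}{latent logit stage propensity = intercept + mother
#'     effect + individual residual; the score is the mean of `n_py_stages`
#'     independent Bernoulli stage indicators, so values are multiples of
#'     `1/n_py_stages` in \[0, 1\].}
#'   \item{subadult_fid}{Gaussian trials: mother effect + offspring effect +
#'     residual, in metres. Possibly negative unless `truncate_fid = TRUE`.}
#'   \item{adult_female_fid}{Gaussian trials on each adult female, grouped by
#'     her own identity (the "mother-as-individual" level).}
#'   \item{subadult_survival}{latent logit liability = intercept + mother
#'     effect + unit-variance residual; the 0/1 outcome is Bernoulli with
#'     probability `plogis(liability)`.}
#' }
#'
#' @param n_mothers Number of mothers with measured offspring.
#' @param n_extra_females Additional adult females with FID trials but no
#'   measured offspring (the study measured more adult females than mothers
#'   of sampled young).
#' @param traits Character vector of traits to generate, a subset of
#'   `c("py_movement", "subadult_fid", "adult_female_fid",
#'   "subadult_survival")`.
#' @param offspring_per_mother,fid_trials_per_subadult,fid_trials_per_mother
#'   Count distributions as `list(min =, max =, mean =)`; counts are drawn
#'   from a Poisson truncated to `[min, max]` with its mean matched to
#'   `mean`.
#' @param n_py_stages Number of binary handling stages for the pouch-young
#'   movement score (8 in the standard protocol, 6 in the abbreviated one).
#' @param mother_cov Mother-level covariance matrix across `traits`
#'   (symmetric positive semidefinite, rows/columns named by trait).
#' @param offspring_var_fid Offspring-level (permanent individual) variance
#'   for subadult FID.
#' @param resid_var Named residual variances per trait. The binary survival
#'   trait always has latent residual variance 1 and the value given here is
#'   ignored for it. For `py_movement` this is the latent stage-propensity
#'   residual variance.
#' @param intercepts Named per-trait intercepts (latent scale for
#'   `py_movement` and `subadult_survival`, metres for the FID traits).
#' @param betas Named list of per-trait fixed-effect coefficients; see
#'   defaults for the recognised term names.
#' @param companion_freq_adult Frequencies of the companion classes for adult
#'   female trials (`alone`, `small_py`, `medium_py`, `large_py`,
#'   `yearling`).
#' @param prob_mother_present_subadult Probability that a subadult FID trial
#'   has the mother in the group.
#' @param years Calendar years over which trials are spread.
#' @param cohorts Birth cohorts for offspring.
#' @param gps_range East-west GPS extent, metres.
#' @param group_size_range Integer range of group sizes.
#' @param days_sentinel Sentinel value of `days_since_prev_test` for an
#'   individual's first FID trial (an arbitrary value larger than any real
#'   gap; 500 days by default).
#' @param prob_observer2_adult Fraction of adult-female trials made by the
#'   second observer.
#' @param truncate_fid If `TRUE`, FID values are truncated at zero.
#' @param adoption_pairs Number of reciprocal rearing-mother swaps applied
#'   via [assign_adoptions()].
#' @param seed Integer seed; the same config and seed always reproduce the
#'   identical dataset.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_dataset()], [assign_adoptions()]
#' @export
sim_config <- function(n_mothers = 111,
                       n_extra_females = 45,
                       traits = c("py_movement", "subadult_fid",
                                  "adult_female_fid", "subadult_survival"),
                       offspring_per_mother = list(min = 1, max = 3, mean = 1.6),
                       fid_trials_per_subadult = list(min = 1, max = 10, mean = 4.6),
                       fid_trials_per_mother = list(min = 1, max = 14, mean = 5.6),
                       n_py_stages = 8,
                       mother_cov = NULL,
                       offspring_var_fid = 3.61,
                       resid_var = c(py_movement = 0.8, subadult_fid = 8.11,
                                     adult_female_fid = 8.5, subadult_survival = 1),
                       intercepts = c(py_movement = qlogis(0.47), subadult_fid = 6.6,
                                      adult_female_fid = 6.6, subadult_survival = 0.97),
                       betas = NULL,
                       companion_freq_adult = c(alone = 0.443, small_py = 0.209,
                                                medium_py = 0.066, large_py = 0.187,
                                                yearling = 0.094),
                       prob_mother_present_subadult = 0.314,
                       years = 2017:2019,
                       cohorts = 2016:2019,
                       gps_range = c(0, 2000),
                       group_size_range = c(1L, 6L),
                       days_sentinel = 500,
                       prob_observer2_adult = 0.09,
                       truncate_fid = FALSE,
                       adoption_pairs = 0L,
                       seed = 1L) {
  traits <- match.arg(traits, all_traits(), several.ok = TRUE)
  if (is.null(mother_cov)) mother_cov <- default_mother_cov(traits)
  if (is.null(betas)) betas <- default_betas(traits)
  cfg <- list(
    n_mothers = as.integer(n_mothers),
    n_extra_females = as.integer(n_extra_females),
    traits = traits,
    offspring_per_mother = offspring_per_mother,
    fid_trials_per_subadult = fid_trials_per_subadult,
    fid_trials_per_mother = fid_trials_per_mother,
    n_py_stages = as.integer(n_py_stages),
    mother_cov = mother_cov,
    offspring_var_fid = offspring_var_fid,
    resid_var = resid_var,
    intercepts = intercepts,
    betas = betas,
    companion_freq_adult = companion_freq_adult,
    prob_mother_present_subadult = prob_mother_present_subadult,
    years = years,
    cohorts = cohorts,
    gps_range = gps_range,
    group_size_range = as.integer(group_size_range),
    days_sentinel = days_sentinel,
    prob_observer2_adult = prob_observer2_adult,
    truncate_fid = isTRUE(truncate_fid),
    adoption_pairs = as.integer(adoption_pairs),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

all_traits <- function() {
  c("py_movement", "subadult_fid", "adult_female_fid", "subadult_survival")
}

# Ground-truth mother-level covariance defaults. FID and survival entries are
# realistic field values for repeated-measures FID (metres^2) and a latent
# logit survival liability; pouch-young movement is on its latent
# stage-propensity (logit) scale with no cross-trait covariance by default.
default_mother_cov <- function(traits = all_traits()) {
  full <- matrix(
    c(1.20, 0.00, 0.00, 0.00,
      0.00, 4.97, 4.14, 1.25,
      0.00, 4.14, 4.78, 0.76,
      0.00, 1.25, 0.76, 1.54),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("py_movement", "subadult_fid", "adult_female_fid", "subadult_survival"),
      c("py_movement", "subadult_fid", "adult_female_fid", "subadult_survival")
    )
  )
  full[traits, traits, drop = FALSE]
}

default_betas <- function(traits = all_traits()) {
  b <- list(
    py_movement = c(age_months = 0.10, sex_female = 0.10, year_effect = 0.05),
    subadult_fid = c(sex_female = 0.50, year_effect = 1.00, gps_east_km = 0.30,
                     group_size = 0.20, companion_mother = 0.30,
                     test_number = -0.10, log_days_since = 0.00,
                     age_months = 0.00),
    adult_female_fid = c(year_effect = 0.80, gps_east_km = 0.30,
                         group_size = 0.20, companion_effect = 0.20,
                         test_number = -0.10, log_days_since = 0.00,
                         observer_2 = 0.50),
    subadult_survival = c(sex_female = -0.20, year_effect = 0.30)
  )
  b[intersect(names(b), traits)]
}

validate_sim_config <- function(cfg) {
  if (cfg$n_mothers < 0L) stop("n_mothers must be >= 0", call. = FALSE)
  if (cfg$n_py_stages < 1L && "py_movement" %in% cfg$traits) {
    stop("n_py_stages must be >= 1", call. = FALSE)
  }
  G <- cfg$mother_cov
  if (!is.matrix(G) || nrow(G) != length(cfg$traits) ||
      is.null(rownames(G)) || !setequal(rownames(G), cfg$traits)) {
    stop("mother_cov must be a matrix with rows/columns named by the configured traits",
         call. = FALSE)
  }
  check_psd(G, "mother_cov")
  rv <- cfg$resid_var[setdiff(cfg$traits, "subadult_survival")]
  if (any(is.na(rv)) || any(rv < 0)) {
    stop("residual variances must be present and >= 0 for every Gaussian/latent trait",
         call. = FALSE)
  }
  if (cfg$offspring_var_fid < 0) stop("offspring_var_fid must be >= 0", call. = FALSE)
  probs <- c(cfg$companion_freq_adult, cfg$prob_mother_present_subadult,
             cfg$prob_observer2_adult)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  invisible(cfg)
}

check_psd <- function(mat, name, tol = 1e-8) {
  if (any(abs(mat - t(mat)) > tol)) {
    stop(sprintf("covariance matrix '%s' is not symmetric", name), call. = FALSE)
  }
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(sprintf("covariance matrix '%s' is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# Draw counts from a Poisson truncated to [min, max], with lambda chosen so
# the truncated mean matches `mean`.
rcount_trunc <- function(n, spec) {
  lo <- spec$min
  hi <- spec$max
  target <- spec$mean
  support <- lo:hi
  if (lo == hi) return(rep(lo, n))
  stopifnot(target >= lo, target <= hi)
  tmean <- function(lam) {
    w <- stats::dpois(support, lam)
    sum(support * w) / sum(w)
  }
  if (target <= lo + 1e-9) {
    probs <- c(1, rep(0, length(support) - 1))
  } else if (target >= hi - 1e-9) {
    probs <- c(rep(0, length(support) - 1), 1)
  } else {
    lam <- stats::uniroot(function(l) tmean(l) - target,
                          lower = 1e-6, upper = 4 * hi)$root
    probs <- stats::dpois(support, lam)
  }
  sample(support, n, replace = TRUE, prob = probs)
}

#' Simulate a long-format behaviour/survival observation table
#'
#' Draws mother-level trait effect vectors from a multivariate normal with
#' the configured mother-level covariance matrix, offspring-level FID effects
#' from a normal, Gaussian trial residuals for the FID traits, pouch-young
#' movement scores via [simulate_py_stage_scores()], and a binary survival
#' outcome through a latent logit liability with unit residual variance.
#' Covariates (sex, year, GPS position, group size, companion class, test
#' number, days since previous test, observer) are drawn per the config.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list with elements `table` (tibble, one row per
#'   trial/measurement — the observation table consumed by [fit_model()] and
#'   [run_full_analysis()]) and `truth` (a `sim_truth` list holding the
#'   generating variance components, coefficients, realized mother and
#'   offspring effects, and the seed).
#' @examples
#' sim <- simulate_dataset(sim_config(n_mothers = 20, n_extra_females = 5, seed = 42))
#' dplyr::count(sim$table, trait)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$n_mothers == 0L) {
    stop("empty design: n_mothers is zero", call. = FALSE)
  }
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  traits <- cfg$traits
  n_m <- cfg$n_mothers
  n_f <- cfg$n_extra_females
  n_all_females <- n_m + n_f
  mother_ids <- sprintf("M%03d", seq_len(n_all_females))

  # mother-level effects for all females (extras only express adult FID)
  L <- chol_psd(cfg$mother_cov[traits, traits, drop = FALSE])
  z <- matrix(rnorm(n_all_females * length(traits)), n_all_females)
  U <- z %*% L
  colnames(U) <- traits

  n_off <- rcount_trunc(n_m, cfg$offspring_per_mother)
  off_mother <- rep(mother_ids[seq_len(n_m)], n_off)
  offspring_ids <- sprintf("O%03d", seq_along(off_mother))
  n_o <- length(offspring_ids)
  v_fid <- rnorm(n_o, 0, sqrt(cfg$offspring_var_fid))
  names(v_fid) <- offspring_ids

  off_sex <- sample(c("male", "female"), n_o, replace = TRUE)
  off_cohort <- sample(cfg$cohorts, n_o, replace = TRUE)

  rows <- list()

  year_dev <- function(yr) yr - min(cfg$years)  # linear year score for the truth betas

  if ("py_movement" %in% traits) {
    b <- cfg$betas$py_movement
    age <- round(rnorm(n_o, 8.0, 0.8), 1)
    yr <- pmin(pmax(off_cohort + 1L, min(cfg$years)), max(cfg$years))
    eta <- cfg$intercepts[["py_movement"]] +
      b[["age_months"]] * (age - 8) +
      b[["sex_female"]] * (off_sex == "female") +
      b[["year_effect"]] * year_dev(yr) +
      U[match(off_mother, mother_ids), "py_movement"]
    score <- simulate_py_stage_scores(
      n_individuals = n_o, mother_effects = rep(0, n_o),
      resid_sd = sqrt(cfg$resid_var[["py_movement"]]),
      n_stages = cfg$n_py_stages, intercept = eta
    )
    rows$py <- tibble::tibble(
      individual_id = offspring_ids, mother_id = off_mother,
      trait = "py_movement", value = as.numeric(score), age_months = age,
      sex = off_sex, year = yr, cohort = off_cohort,
      gps_east_m = NA_real_, group_size = NA_integer_,
      companion_class = NA_character_, test_number = 1L,
      days_since_prev_test = NA_real_, observer_id = "obs1"
    )
  }

  if ("subadult_fid" %in% traits) {
    b <- cfg$betas$subadult_fid
    k <- rcount_trunc(n_o, cfg$fid_trials_per_subadult)
    idx <- rep(seq_len(n_o), k)
    test_no <- sequence(k)
    age <- round(runif(length(idx), 13, 35))
    yr <- sample(cfg$years, length(idx), replace = TRUE)
    gps <- runif(length(idx), cfg$gps_range[1], cfg$gps_range[2])
    gsz <- sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
                  length(idx), replace = TRUE)
    comp <- ifelse(runif(length(idx)) < cfg$prob_mother_present_subadult,
                   "mother_present", "alone")
    days <- ifelse(test_no == 1L, cfg$days_sentinel, round(runif(length(idx), 7, 365)))
    eta <- cfg$intercepts[["subadult_fid"]] +
      b[["sex_female"]] * (off_sex[idx] == "female") +
      b[["year_effect"]] * year_dev(yr) +
      b[["gps_east_km"]] * gps / 1000 +
      b[["group_size"]] * (gsz - 1) +
      b[["companion_mother"]] * (comp == "mother_present") +
      b[["test_number"]] * (test_no - 1) +
      b[["log_days_since"]] * log(days) +
      b[["age_months"]] * (age - 24) +
      U[match(off_mother[idx], mother_ids), "subadult_fid"] +
      v_fid[idx]
    val <- as.numeric(eta + rnorm(length(idx), 0, sqrt(cfg$resid_var[["subadult_fid"]])))
    if (cfg$truncate_fid) val <- pmax(val, 0)
    rows$sfid <- tibble::tibble(
      individual_id = offspring_ids[idx], mother_id = off_mother[idx],
      trait = "subadult_fid", value = val, age_months = age,
      sex = off_sex[idx], year = yr, cohort = off_cohort[idx],
      gps_east_m = gps, group_size = gsz, companion_class = comp,
      test_number = test_no, days_since_prev_test = days, observer_id = "obs1"
    )
  }

  if ("adult_female_fid" %in% traits) {
    b <- cfg$betas$adult_female_fid
    k <- rcount_trunc(n_all_females, cfg$fid_trials_per_mother)
    idx <- rep(seq_len(n_all_females), k)
    test_no <- sequence(k)
    yr <- sample(cfg$years, length(idx), replace = TRUE)
    gps <- runif(length(idx), cfg$gps_range[1], cfg$gps_range[2])
    gsz <- sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
                  length(idx), replace = TRUE)
    comp <- sample(names(cfg$companion_freq_adult), length(idx), replace = TRUE,
                   prob = cfg$companion_freq_adult)
    days <- ifelse(test_no == 1L, cfg$days_sentinel, round(runif(length(idx), 7, 365)))
    obs <- ifelse(runif(length(idx)) < cfg$prob_observer2_adult, "obs2", "obs1")
    eta <- cfg$intercepts[["adult_female_fid"]] +
      b[["year_effect"]] * year_dev(yr) +
      b[["gps_east_km"]] * gps / 1000 +
      b[["group_size"]] * (gsz - 1) +
      b[["companion_effect"]] * (comp != "alone") +
      b[["test_number"]] * (test_no - 1) +
      b[["log_days_since"]] * log(days) +
      b[["observer_2"]] * (obs == "obs2") +
      U[idx, "adult_female_fid"]
    val <- as.numeric(eta + rnorm(length(idx), 0, sqrt(cfg$resid_var[["adult_female_fid"]])))
    if (cfg$truncate_fid) val <- pmax(val, 0)
    rows$afid <- tibble::tibble(
      individual_id = mother_ids[idx], mother_id = mother_ids[idx],
      trait = "adult_female_fid", value = val, age_months = NA_real_,
      sex = "female", year = yr, cohort = NA_integer_,
      gps_east_m = gps, group_size = gsz, companion_class = comp,
      test_number = test_no, days_since_prev_test = days, observer_id = obs
    )
  }

  if ("subadult_survival" %in% traits) {
    b <- cfg$betas$subadult_survival
    yr <- off_cohort
    eta <- cfg$intercepts[["subadult_survival"]] +
      b[["sex_female"]] * (off_sex == "female") +
      b[["year_effect"]] * (yr - min(cfg$cohorts)) +
      U[match(off_mother, mother_ids), "subadult_survival"]
    liab <- as.numeric(eta + rnorm(n_o, 0, 1))
    surv <- rbinom(n_o, 1, plogis(liab))
    rows$surv <- tibble::tibble(
      individual_id = offspring_ids, mother_id = off_mother,
      trait = "subadult_survival", value = as.numeric(surv), age_months = NA_real_,
      sex = off_sex, year = yr, cohort = off_cohort,
      gps_east_m = NA_real_, group_size = NA_integer_,
      companion_class = NA_character_, test_number = 1L,
      days_since_prev_test = NA_real_, observer_id = "obs1"
    )
  }

  table <- dplyr::bind_rows(rows)
  table <- dplyr::mutate(
    table,
    observation_id = sprintf("obs%05d", dplyr::row_number()),
    biological_mother_id = ifelse(.data$individual_id %in% offspring_ids,
                                  .data$mother_id, NA_character_),
    rearing_mother_id = .data$biological_mother_id
  )
  table <- dplyr::select(
    table, "observation_id", "individual_id", "mother_id",
    "biological_mother_id", "rearing_mother_id", "trait", "value",
    "age_months", "sex", "year", "cohort", "gps_east_m", "group_size",
    "companion_class", "test_number", "days_since_prev_test", "observer_id"
  )

  truth <- structure(list(
    seed = cfg$seed,
    traits = traits,
    mother_cov = cfg$mother_cov[traits, traits, drop = FALSE],
    offspring_var_fid = cfg$offspring_var_fid,
    resid_var = cfg$resid_var,
    intercepts = cfg$intercepts,
    betas = cfg$betas,
    mother_effects = tibble::tibble(
      mother_id = mother_ids,
      tibble::as_tibble(as.data.frame(U))
    ),
    offspring_effects = tibble::tibble(
      individual_id = offspring_ids,
      mother_id = off_mother,
      fid_effect = unname(v_fid)
    ),
    config = cfg
  ), class = "sim_truth")

  if (cfg$adoption_pairs > 0L) {
    table <- assign_adoptions(table, cfg$adoption_pairs, seed = cfg$seed + 1L)
  }

  list(table = table, truth = truth)
}

# Upper-triangular Cholesky factor tolerant of semidefinite matrices.
chol_psd <- function(S) {
  ok <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  R <- diag(sqrt(vals), nrow = length(vals)) %*% t(e$vectors)
  R
}

#' Simulate pouch-young movement scores from binary handling stages
#'
#' Each individual has a latent logit stage propensity
#' `intercept + mother_effect + N(0, resid_sd^2)`. Stage indicators are
#' independent Bernoulli draws with that propensity, and the score is the
#' mean of the indicators — a multiple of `1/n_stages` in \[0, 1\].
#'
#' @param n_individuals Number of individuals to score.
#' @param mother_effects Numeric vector of per-individual mother-level latent
#'   effects (length 1 or `n_individuals`).
#' @param resid_sd Standard deviation of the individual latent residual.
#' @param n_stages Number of binary handling stages (>= 1); 8 in the
#'   standard protocol, 6 in the abbreviated one.
#' @param intercept Latent intercept (length 1 or `n_individuals`).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#'
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' simulate_py_stage_scores(5, mother_effects = 0, resid_sd = 1, n_stages = 8, seed = 1)
#' @export
simulate_py_stage_scores <- function(n_individuals, mother_effects, resid_sd,
                                     n_stages = 8, intercept = 0, seed = NULL) {
  if (n_stages < 1) stop("n_stages must be >= 1", call. = FALSE)
  n <- as.integer(n_individuals)
  with_seed(seed, {
    eta <- intercept + mother_effects + rnorm(n, 0, resid_sd)
    p <- plogis(eta)
    rbinom(n, size = n_stages, prob = p) / n_stages
  })
}

#' Swap rearing mothers to emulate adoption (cross-fostering)
#'
#' For `n_pairs` randomly chosen pairs of offspring with distinct mothers,
#' reciprocally swaps `rearing_mother_id` (and the model grouping column
#' `mother_id`, which follows the rearing mother) between the two offspring,
#' leaving `biological_mother_id` intact. The multiset of rearing mothers is
#' conserved.
#'
#' @param table An observation table (see [simulate_dataset()]).
#' @param n_pairs Number of reciprocal swaps.
#' @param seed Optional seed.
#'
#' @return The table with swapped rearing assignments.
#' @export
assign_adoptions <- function(table, n_pairs, seed = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs == 0L) return(table)
  off <- dplyr::distinct(
    dplyr::filter(table, !is.na(.data$biological_mother_id)),
    .data$individual_id, .data$biological_mother_id
  )
  with_seed(seed, {
    chosen <- character(0)
    pairs <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      pool <- dplyr::filter(off, !(.data$individual_id %in% chosen))
      a <- pool[sample(nrow(pool), 1L), ]
      pool2 <- dplyr::filter(pool, .data$biological_mother_id != a$biological_mother_id,
                             .data$individual_id != a$individual_id)
      if (nrow(pool2) == 0L) {
        stop("insufficient eligible offspring with distinct mothers for the requested swaps",
             call. = FALSE)
      }
      b <- pool2[sample(nrow(pool2), 1L), ]
      chosen <- c(chosen, a$individual_id, b$individual_id)
      pairs[[i]] <- c(a$individual_id, b$individual_id)
    }
    if (length(chosen) < 2L * n_pairs) {
      stop("insufficient eligible offspring for the requested swaps", call. = FALSE)
    }
    for (pr in pairs) {
      ia <- table$individual_id == pr[1] & !is.na(table$biological_mother_id)
      ib <- table$individual_id == pr[2] & !is.na(table$biological_mother_id)
      ma <- table$rearing_mother_id[ia][1]
      mb <- table$rearing_mother_id[ib][1]
      table$rearing_mother_id[ia] <- mb
      table$rearing_mother_id[ib] <- ma
      table$mother_id[ia] <- mb
      table$mother_id[ib] <- ma
    }
    table
  })
}
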