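#' Collapse repeated subadult FID trials to one mean value per offspring
#'
#' The four-trait model represents each offspring by a single value per
#' trait, so repeated subadult FID trials are averaged into one row.
#' Trial-varying covariates (test number, group size, companion class, days
#' since previous test, GPS position) are dropped for that trait;
#' individual-level covariates keep the first trial's values and
#' `age_months` becomes the mean testing age. Other traits are untouched.
#'
#' @param table An observation table.
#' @return The table with one `subadult_fid` row per offspring.
#' @export
average_subadult_fid <- function(table) {
  fid <- dplyr::filter(table, .data$trait == "subadult_fid")
  if (!nrow(fid)) return(table)
  rest <- dplyr::filter(table, .data$trait != "subadult_fid")
  avg <- fid |>
    dplyr::arrange(.data$individual_id, .data$test_number) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      observation_id = dplyr::first(.data$observation_id),
      mother_id = dplyr::first(.data$mother_id),
      biological_mother_id = dplyr::first(.data$biological_mother_id),
      rearing_mother_id = dplyr::first(.data$rearing_mother_id),
      trait = "subadult_fid",
      value = mean(.data$value),
      age_months = mean(.data$age_months),
      sex = dplyr::first(.data$sex),
      year = dplyr::first(.data$year),
      cohort = dplyr::first(.data$cohort),
      gps_east_m = NA_real_,
      group_size = NA_integer_,
      companion_class = NA_character_,
      test_number = 1L,
      days_since_prev_test = NA_real_,
      observer_id = dplyr::first(.data$observer_id),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(names(table)))
  dplyr::bind_rows(rest, avg)
}

#' Four-trait model specification (pouch-young movement, mean subadult FID,
#' survival, adult-female FID)
#'
#' Builds the joint model of all four traits with a mother-level random
#' effect and unstructured 4x4 mother covariance. The three offspring traits
#' share unit-level (per-offspring) residual vectors with free covariance;
#' adult-female FID is measured on different units (the females' own
#' repeated trials), so its residual covariance with the offspring traits is
#' fixed to zero. The binary survival trait has its latent residual variance
#' fixed at 1. Expects subadult FID already averaged
#' ([average_subadult_fid()]).
#'
#' @param table Observation table containing all four traits.
#' @param fixed_effects Optional named list of per-trait covariate
#'   overrides.
#' @param prior Optional prior overrides (see [model_spec()]).
#' @return A [model_spec()].
#' @export
model_spec_four_trait <- function(table, fixed_effects = NULL, prior = NULL) {
  needed <- c("py_movement", "subadult_fid", "adult_female_fid", "subadult_survival")
  present <- unique(table$trait)
  if (!all(needed %in% present)) {
    stop("missing trait(s) for the four-trait model: ",
         paste(setdiff(needed, present), collapse = ", "), call. = FALSE)
  }
  fe <- list(
    py_movement = c("age_months", "sex", "year"),
    subadult_fid = c("sex", "year"),
    subadult_survival = c("sex", "year"),
    adult_female_fid = c("gps_east_km", "group_size", "companion_class",
                         "test_number", "days_since_prev_test", "year",
                         "observer_id")
  )
  fe <- utils::modifyList(fe, fixed_effects %||% list())
  model_spec(
    traits = list(
      trait_spec("py_movement", "gaussian", fe$py_movement, random = "mother"),
      trait_spec("subadult_fid", "gaussian", fe$subadult_fid, random = "mother"),
      trait_spec("subadult_survival", "binary_logit", fe$subadult_survival,
                 random = "mother"),
      trait_spec("adult_female_fid", "gaussian", fe$adult_female_fid,
                 random = "mother")
    ),
    resid_groups = list(c("py_movement", "subadult_fid", "subadult_survival")),
    prior = prior
  )
}

#' Bivariate repeated-measures FID model specification
#'
#' Subadult FID and adult-female FID with repeated trials on both: a
#' mother-level random effect on both traits (unstructured 2x2 covariance),
#' an offspring-level effect on subadult FID only, and residual cross-trait
#' covariance fixed to zero (the traits are observed on different trials, so
#' within-unit residuals cannot covary).
#'
#' @inheritParams model_spec_four_trait
#' @return A [model_spec()].
#' @export
model_spec_bivariate_fid <- function(table, fixed_effects = NULL, prior = NULL) {
  needed <- c("subadult_fid", "adult_female_fid")
  present <- unique(table$trait)
  if (!all(needed %in% present)) {
    stop("missing trait(s) for the bivariate FID model: ",
         paste(setdiff(needed, present), collapse = ", "), call. = FALSE)
  }
  fe <- list(
    subadult_fid = c("gps_east_km", "group_size", "companion_class",
                     "test_number", "days_since_prev_test", "year",
                     "age_months", "sex"),
    adult_female_fid = c("gps_east_km", "group_size", "companion_class",
                         "test_number", "days_since_prev_test", "year",
                         "observer_id")
  )
  fe <- utils::modifyList(fe, fixed_effects %||% list())
  model_spec(
    traits = list(
      trait_spec("subadult_fid", "gaussian", fe$subadult_fid,
                 random = c("mother", "individual")),
      trait_spec("adult_female_fid", "gaussian", fe$adult_female_fid,
                 random = "mother")
    ),
    prior = prior
  )
}

#' Run the full two-model variance-partitioning analysis
#'
#' Fits the four-trait model (on averaged subadult FID) and the bivariate
#' repeated-measures FID model, computes repeatability decompositions for
#' every trait, converts the binary survival components to the data scale,
#' estimates the upper-limit heritability of FID from the bivariate model,
#' and - when the table contains cross-fostered offspring - the
#' mother-offspring adoption regression.
#'
#' @param table Observation table.
#' @param mcmc An [mcmc_config()]; the bivariate model uses `seed + 1`.
#' @param models Character subset of `c("I", "II")`: `"I"` is the four-trait
#'   model, `"II"` the bivariate FID model.
#' @param quiet Suppress low-ESS warnings from the fits.
#' @return An `analysis_report` list with elements `model_I`, `model_II`
#'   (each: `fit`, `fixed_effects`, `covariances`, `decompositions`),
#'   `survival_data_scale`, `heritability`, `adoption`, and `meta`.
#' @export
run_full_analysis <- function(table, mcmc = mcmc_config(), models = c("I", "II"),
                              quiet = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  report <- list(meta = list(
    seed = mcmc$seed, n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
    thin = mcmc$thin,
    n_rows = nrow(table),
    traits = sort(unique(table$trait))
  ))

  if ("I" %in% models) {
    report$model_I <- tryCatch({
      tab1 <- average_subadult_fid(table)
      spec1 <- model_spec_four_trait(tab1)
      fit1 <- fit_model(tab1, spec1, mcmc, quiet = quiet)
      dec <- lapply(c("py_movement", "subadult_fid", "subadult_survival",
                      "adult_female_fid"),
                    function(t) decompose_variance(fit1, t))
      names(dec) <- c("py_movement", "subadult_fid", "subadult_survival",
                      "adult_female_fid")
      sds <- data_scale_posterior(fit1, tab1, "subadult_survival")
      list(fit = fit1,
           fixed_effects = fixed_effect_summary(fit1),
           covariances = covariance_summary(fit1),
           decompositions = dec,
           survival_data_scale = dplyr::bind_cols(
             summarize_ratio(sds$repeatability_data),
             tibble::tibble(scale = "data")
           ),
           survival_latent_scale = dplyr::bind_cols(
             summarize_ratio(sds$repeatability_latent),
             tibble::tibble(scale = "latent")
           ))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  if ("II" %in% models) {
    mcmc2 <- mcmc
    mcmc2$seed <- mcmc$seed + 1L
    report$model_II <- tryCatch({
      spec2 <- model_spec_bivariate_fid(table)
      fit2 <- fit_model(table, spec2, mcmc2, quiet = quiet)
      dec <- list(
        subadult_fid = decompose_variance(fit2, "subadult_fid"),
        adult_female_fid = decompose_variance(fit2, "adult_female_fid")
      )
      list(fit = fit2,
           fixed_effects = fixed_effect_summary(fit2),
           covariances = covariance_summary(fit2),
           decompositions = dec,
           heritability = upper_limit_h2(fit2))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  has_adoption <- any(!is.na(table$rearing_mother_id) &
                        !is.na(table$biological_mother_id) &
                        table$rearing_mother_id != table$biological_mother_id)
  if (has_adoption) {
    report$adoption <- tryCatch(adoption_regression(table),
                                error = function(e) list(error = conditionMessage(e)))
  }

  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Variance-partitioning analysis report\n")
  cat(sprintf("  seed %d, %d MCMC iterations\n", x$meta$seed, x$meta$n_iter))
  for (m in c("model_I", "model_II")) {
    if (is.null(x[[m]])) next
    if (!is.null(x[[m]]$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", m, x[[m]]$error))
    } else {
      cat(sprintf("  %s: %d parameters summarised\n", m,
                  nrow(x[[m]]$covariances) + nrow(x[[m]]$fixed_effects)))
    }
  }
  if (!is.null(x$model_II$heritability) && is.null(x$model_II$error)) {
    h <- x$model_II$heritability
    cat(sprintf("  upper-limit h2 (FID): %.2f (%.2f, %.2f)\n",
                h$posterior_mode, h$hpd_low, h$hpd_high))
  }
  invisible(x)
}

#' Per-animal mean FIDs for mother-offspring comparison
#'
#' One row per offspring with a measured subadult FID: the offspring's mean
#' FID alongside the mean adult FID of its biological and rearing mothers
#' (the scatter underlying a mother-offspring FID regression).
#'
#' @param table Observation table.
#' @return A tibble `individual_id`, `biological_mother_id`,
#'   `rearing_mother_id`, `offspring_fid`, `biological_mother_fid`,
#'   `rearing_mother_fid`, `adopted`.
#' @export
fid_mother_offspring_means <- function(table) {
  off <- table |>
    dplyr::filter(.data$trait == "subadult_fid") |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      biological_mother_id = dplyr::first(.data$biological_mother_id),
      rearing_mother_id = dplyr::first(.data$rearing_mother_id),
      offspring_fid = mean(.data$value), .groups = "drop"
    )
  mum <- table |>
    dplyr::filter(.data$trait == "adult_female_fid") |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(mother_fid = mean(.data$value), .groups = "drop")
  out <- off |>
    dplyr::left_join(dplyr::rename(mum, biological_mother_id = "individual_id",
                                   biological_mother_fid = "mother_fid"),
                     by = "biological_mother_id") |>
    dplyr::left_join(dplyr::rename(mum, rearing_mother_id = "individual_id",
                                   rearing_mother_fid = "mother_fid"),
                     by = "rearing_mother_id") |>
    dplyr::mutate(adopted = !is.na(.data$biological_mother_id) &
                    !is.na(.data$rearing_mother_id) &
                    .data$biological_mother_id != .data$rearing_mother_id)
  class(out) <- c("fid_means", class(out))
  out
}

#' Mother-offspring FID regression on cross-fostered offspring
#'
#' Ordinary least-squares regression of offspring mean FID on (a) the
#' biological mother's and (b) the rearing (adoptive) mother's mean FID,
#' restricted to offspring reared by a non-biological mother with FID
#' measured on the offspring and both mothers. Slopes are doubled to give
#' upper-limit heritability estimates, with correspondingly doubled
#' confidence intervals. With the handful of adoptions such populations
#' offer, intervals are expected to be very wide.
#'
#' @param table Observation table.
#' @param min_cases Minimum number of usable adopted offspring (default 3).
#' @param level Confidence level.
#' @return A tibble with one row per mother type: `mother_type`, `n`,
#'   `slope`, `upper_h2`, `conf_low`, `conf_high` (the latter three on the
#'   doubled scale).
#' @export
adoption_regression <- function(table, min_cases = 3, level = 0.95) {
  d <- fid_mother_offspring_means(table)
  d <- dplyr::filter(d, .data$adopted,
                     !is.na(.data$offspring_fid),
                     !is.na(.data$biological_mother_fid),
                     !is.na(.data$rearing_mother_fid))
  if (nrow(d) < min_cases) {
    stop(sprintf("adoption regression needs at least %d cross-fostered offspring with FID on the offspring and both mothers (found %d)",
                 min_cases, nrow(d)), call. = FALSE)
  }
  one <- function(x, label) {
    fit <- lm(d$offspring_fid ~ x)
    ci <- confint(fit, level = level)[2, ]
    tibble::tibble(mother_type = label, n = nrow(d),
                   slope = unname(coef(fit)[2]),
                   upper_h2 = 2 * unname(coef(fit)[2]),
                   conf_low = 2 * ci[[1]], conf_high = 2 * ci[[2]])
  }
  dplyr::bind_rows(one(d$biological_mother_fid, "biological"),
                   one(d$rearing_mother_fid, "rearing"))
}
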