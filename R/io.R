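observation_columns <- function() {
  c("observation_id", "individual_id", "mother_id", "biological_mother_id",
    "rearing_mother_id", "trait", "value", "age_months", "sex", "year",
    "cohort", "gps_east_m", "group_size", "companion_class", "test_number",
    "days_since_prev_test", "observer_id")
}

#' Read and validate an observation table from CSV
#'
#' CSV dialect: comma-separated, UTF-8, header required, missing values as
#' the empty string. Validates the canonical columns, value ranges (binary
#' survival in \{0, 1\}, pouch-young movement scores multiples of
#' `1/n_py_stages` in \[0, 1\]) and that each individual maps to exactly one
#' biological mother; violations are reported with the offending CSV line
#' number (header = line 1).
#'
#' @param path CSV file path.
#' @param n_py_stages Stage count used for the score-multiple check.
#' @param strict_scores Disable to accept pouch-young scores that are not
#'   exact stage multiples.
#' @return A validated tibble.
#' @export
read_observations <- function(path, n_py_stages = 8, strict_scores = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!nrow(df)) stop("empty observation file: ", path, call. = FALSE)
  missing <- setdiff(observation_columns(), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, observation_columns()]
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  out <- tibble::tibble(
    observation_id = df$observation_id,
    individual_id = df$individual_id,
    mother_id = df$mother_id,
    biological_mother_id = df$biological_mother_id,
    rearing_mother_id = df$rearing_mother_id,
    trait = df$trait,
    value = num(df$value),
    age_months = num(df$age_months),
    sex = df$sex,
    year = int(df$year),
    cohort = int(df$cohort),
    gps_east_m = num(df$gps_east_m),
    group_size = int(df$group_size),
    companion_class = df$companion_class,
    test_number = int(df$test_number),
    days_since_prev_test = num(df$days_since_prev_test),
    observer_id = df$observer_id
  )
  line <- seq_len(nrow(out)) + 1L  # CSV line numbers (header is line 1)
  fail <- function(rows, msg) {
    if (any(rows)) {
      stop(sprintf("%s (line%s %s)", msg, if (sum(rows) > 1) "s" else "",
                   paste(head(line[rows], 10), collapse = ", ")), call. = FALSE)
    }
  }
  fail(is.na(out$trait) | !nzchar(out$trait), "missing trait name")
  fail(is.na(out$value) & !is.na(df$value), "non-numeric value")
  fail(is.na(out$value), "missing value")
  surv <- out$trait == "subadult_survival"
  fail(surv & !(out$value %in% c(0, 1)), "subadult_survival values must be 0 or 1")
  if (strict_scores) {
    py <- out$trait == "py_movement"
    mult <- out$value * n_py_stages
    fail(py & (out$value < 0 | out$value > 1 |
                 abs(mult - round(mult)) > 1e-8),
         sprintf("py_movement scores must be multiples of 1/%d in [0,1]", n_py_stages))
  }
  fail(is.na(out$individual_id), "missing individual_id")
  # one biological mother per individual
  bm <- out[!is.na(out$biological_mother_id),
            c("individual_id", "biological_mother_id")]
  multi <- tapply(bm$biological_mother_id, bm$individual_id,
                  function(x) length(unique(x)))
  if (any(multi > 1)) {
    stop("individual(s) with multiple biological mothers: ",
         paste(names(multi)[multi > 1], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: comma-separated, header, missing values
#' as empty strings.
#'
#' @param table Observation table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, observation_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Serialise posterior draws as tidy CSV
#'
#' Long format with columns `iteration`, `parameter_name`, `value`;
#' round-trips through [read_posterior()].
#'
#' @param x An `mt_fit` or a long tidy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(x, path) {
  if (inherits(x, "mt_fit")) x <- tidy(x)
  stopifnot(all(c("iteration", "parameter_name", "value") %in% names(x)))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_posterior
#' @return For `read_posterior()`: the long tibble.
#' @export
read_posterior <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  stopifnot(all(c("iteration", "parameter_name", "value") %in% names(df)))
  tibble::tibble(iteration = as.integer(df$iteration),
                 parameter_name = as.character(df$parameter_name),
                 value = as.numeric(df$value))
}

#' Write the generating truth of a simulated dataset as JSON
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list(
    seed = truth$seed,
    traits = truth$traits,
    mother_cov = as.data.frame(truth$mother_cov),
    offspring_var_fid = truth$offspring_var_fid,
    resid_var = as.list(truth$resid_var),
    intercepts = as.list(truth$intercepts),
    betas = lapply(truth$betas, as.list),
    mother_effects = as.data.frame(truth$mother_effects),
    offspring_effects = as.data.frame(truth$offspring_effects)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serialises the summary tables of an `analysis_report` (fits themselves
#' are omitted; persist them with [write_posterior()]).
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.null(m$error)) return(list(error = m$error))
    out <- list(
      fixed_effects = as.data.frame(m$fixed_effects),
      covariances = as.data.frame(m$covariances),
      decompositions = lapply(m$decompositions, as.data.frame)
    )
    for (nm in c("survival_data_scale", "survival_latent_scale", "heritability")) {
      if (!is.null(m[[nm]])) out[[nm]] <- as.data.frame(m[[nm]])
    }
    out
  }
  out <- list(meta = report$meta,
              model_I = strip(report$model_I),
              model_II = strip(report$model_II))
  if (!is.null(report$adoption)) out$adoption <- as.data.frame(report$adoption)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
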