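# Shared fixtures: tiny observation tables built in code.

obs_row_defaults <- function(n) {
  tibble::tibble(
    observation_id = sprintf("o%04d", seq_len(n)),
    individual_id = sprintf("i%04d", seq_len(n)),
    mother_id = NA_character_,
    biological_mother_id = NA_character_,
    rearing_mother_id = NA_character_,
    trait = "resp",
    value = 0,
    age_months = NA_real_,
    sex = "male",
    year = 2017L,
    cohort = NA_integer_,
    gps_east_m = NA_real_,
    group_size = NA_integer_,
    companion_class = NA_character_,
    test_number = 1L,
    days_since_prev_test = NA_real_,
    observer_id = "obs1"
  )
}

# single Gaussian trait, k mothers x m obs each, known components
one_way_table <- function(k, m, var_mother, var_resid, mu = 5, seed = 1) {
  withr::with_seed(seed, {
    n <- k * m
    tab <- obs_row_defaults(n)
    mid <- rep(sprintf("m%03d", seq_len(k)), each = m)
    u <- rep(rnorm(k, 0, sqrt(var_mother)), each = m)
    tab$mother_id <- mid
    tab$biological_mother_id <- mid
    tab$rearing_mother_id <- mid
    tab$value <- mu + u + rnorm(n, 0, sqrt(var_resid))
    tab
  })
}

# method-of-moments one-way ANOVA estimator (independent of the sampler)
anova_components <- function(values, groups) {
  k <- length(unique(groups))
  n <- length(values)
  m <- n / k
  gm <- tapply(values, groups, mean)
  msb <- m * stats::var(gm)
  msw <- sum((values - gm[groups])^2) / (n - k)
  c(var_mother = (msb - msw) / m, var_resid = msw)
}

bivariate_fid_config <- function(seed, n_mothers = 95, n_extra = 55,
                                 offspring_mean = 1.05) {
  nm <- c("subadult_fid", "adult_female_fid")
  sim_config(
    n_mothers = n_mothers, n_extra_females = n_extra, traits = nm,
    offspring_per_mother = list(min = 1, max = 3, mean = offspring_mean),
    mother_cov = matrix(c(5, 4, 4, 5), 2, dimnames = list(nm, nm)),
    offspring_var_fid = 3.6,
    resid_var = c(subadult_fid = 8, adult_female_fid = 8),
    seed = seed
  )
}
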