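test_that("the same config and seed reproduce an identical dataset", {
  cfg <- sim_config(n_mothers = 25, n_extra_females = 5, seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$mother_effects, b$truth$mother_effects)
})

test_that("config validation rejects bad inputs", {
  nm <- c("subadult_fid", "adult_female_fid")
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(nm, nm))  # cor = 2
  expect_error(sim_config(traits = nm, mother_cov = bad), "positive semidefinite")
  expect_error(simulate_dataset(sim_config(n_mothers = 0)), "empty design")
  expect_error(sim_config(prob_observer2_adult = 1.4), "probabilities")
})

zero_betas <- function(traits) {
  b <- maternalvar:::default_betas(traits)
  lapply(b, function(x) x * 0)
}

test_that("zero mother-level variance leaves only sampling noise between mothers", {
  nm <- "subadult_fid"
  cfg <- sim_config(
    n_mothers = 300, n_extra_females = 0, traits = nm,
    mother_cov = matrix(0, 1, 1, dimnames = list(nm, nm)),
    offspring_per_mother = list(min = 1, max = 1, mean = 1),
    fid_trials_per_subadult = list(min = 5, max = 5, mean = 5),
    offspring_var_fid = 0, resid_var = c(subadult_fid = 8),
    betas = zero_betas(nm), seed = 3
  )
  tab <- simulate_dataset(cfg)$table
  mother_means <- tapply(tab$value, tab$mother_id, mean)
  # Var(mean of 5 trials) = 8 / 5 = 1.6; between-mother variance should match
  expect_lt(abs(var(mother_means) - 1.6), 0.4)
})

test_that("nested variance components are recovered by a moments oracle", {
  nm <- "subadult_fid"
  cfg <- sim_config(
    n_mothers = 200, n_extra_females = 0, traits = nm,
    mother_cov = matrix(5, 1, 1, dimnames = list(nm, nm)),
    offspring_per_mother = list(min = 2, max = 2, mean = 2),
    fid_trials_per_subadult = list(min = 5, max = 5, mean = 5),
    offspring_var_fid = 3.6, resid_var = c(subadult_fid = 8),
    betas = zero_betas(nm), seed = 7
  )
  tab <- simulate_dataset(cfg)$table
  # balanced nested ANOVA (mothers / offspring / trials), moments estimators
  k <- 200; o <- 2; tr <- 5
  mom_mean <- tapply(tab$value, tab$mother_id, mean)
  off_mean <- tapply(tab$value, tab$individual_id, mean)
  off_mother <- tapply(tab$mother_id, tab$individual_id, function(x) x[1])
  ms_resid <- sum((tab$value - off_mean[tab$individual_id])^2) / (k * o * (tr - 1))
  ms_off <- tr * sum((off_mean - mom_mean[off_mother])^2) / (k * (o - 1))
  ms_mom <- o * tr * sum((mom_mean - mean(tab$value))^2) / (k - 1)
  est <- c(mother = (ms_mom - ms_off) / (o * tr),
           offspring = (ms_off - ms_resid) / tr,
           resid = ms_resid)
  expect_lt(abs(est[["mother"]] - 5) / 5, 0.15)
  expect_lt(abs(est[["offspring"]] - 3.6) / 3.6, 0.15)
  expect_lt(abs(est[["resid"]] - 8) / 8, 0.15)
})

test_that("pouch-young stage scores follow binomial moments and stage multiples", {
  s <- simulate_py_stage_scores(20000, mother_effects = 0, resid_sd = 0,
                                n_stages = 8, intercept = 0, seed = 1)
  expect_lt(abs(mean(s) - 0.5), 0.01)
  expect_lt(abs(var(s) - 0.25 / 8), 0.002)
  s6 <- simulate_py_stage_scores(500, mother_effects = 0, resid_sd = 1,
                                 n_stages = 6, intercept = 0, seed = 2)
  expect_true(all(abs(s6 * 6 - round(s6 * 6)) < 1e-12))
  expect_true(all(s6 >= 0 & s6 <= 1))
  s0 <- simulate_py_stage_scores(100, mother_effects = 0, resid_sd = 0,
                                 n_stages = 8, intercept = -50, seed = 3)
  expect_true(all(s0 == 0))
  expect_error(simulate_py_stage_scores(10, 0, 1, n_stages = 0), "n_stages")
})

test_that("adoption swaps rearing mothers reciprocally and conserve the multiset", {
  sim <- simulate_dataset(sim_config(n_mothers = 30, n_extra_females = 0, seed = 11))
  tab <- sim$table
  expect_identical(assign_adoptions(tab, 0), tab)
  sw <- assign_adoptions(tab, 2, seed = 4)
  off <- dplyr::distinct(dplyr::filter(sw, !is.na(sw$biological_mother_id)),
                         individual_id, biological_mother_id, rearing_mother_id)
  expect_identical(sum(off$rearing_mother_id != off$biological_mother_id), 4L)
  # per-offspring multiset of rearing mothers is conserved by the swaps
  off0 <- dplyr::distinct(dplyr::filter(tab, !is.na(tab$biological_mother_id)),
                          individual_id, rearing_mother_id)
  expect_identical(sort(off$rearing_mother_id), sort(off0$rearing_mother_id))
  # grouping column follows the rearing mother
  expect_identical(sw$mother_id[!is.na(sw$biological_mother_id)],
                   sw$rearing_mother_id[!is.na(sw$biological_mother_id)])
})

test_that("large mother-level variance drives the intraclass correlation toward 1", {
  nm <- "subadult_fid"
  cfg <- sim_config(
    n_mothers = 100, n_extra_females = 0, traits = nm,
    mother_cov = matrix(400, 1, 1, dimnames = list(nm, nm)),
    offspring_per_mother = list(min = 2, max = 2, mean = 2),
    fid_trials_per_subadult = list(min = 3, max = 3, mean = 3),
    offspring_var_fid = 1, resid_var = c(subadult_fid = 1),
    betas = zero_betas(nm), seed = 5
  )
  tab <- simulate_dataset(cfg)$table
  est <- anova_components(tab$value, tab$mother_id)
  icc <- est[["var_mother"]] / sum(est)
  expect_gt(icc, 0.95)
})

test_that("empirical survival matches the logit-liability closed form", {
  nm <- "subadult_survival"
  cfg <- sim_config(
    n_mothers = 600, n_extra_females = 0, traits = nm,
    mother_cov = matrix(1.54, 1, 1, dimnames = list(nm, nm)),
    offspring_per_mother = list(min = 2, max = 2, mean = 2),
    betas = list(subadult_survival = c(sex_female = 0, year_effect = 0)),
    seed = 9
  )
  tab <- simulate_dataset(cfg)$table
  expected <- data_scale_components(1.54, 1, latent_means = 0.97)$expected_phenotype
  se <- sqrt(expected * (1 - expected) / nrow(tab)) * 2  # clustered; inflate
  expect_lt(abs(mean(tab$value) - expected), 4 * se)
})
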