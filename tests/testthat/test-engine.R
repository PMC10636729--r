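test_that("with no random effects and fixed residual variance the posterior matches GLS", {
  tab <- withr::with_seed(3, {
    t0 <- obs_row_defaults(40)
    t0$age_months <- runif(40, -2, 2)
    t0$value <- 2 + 0.5 * t0$age_months + rnorm(40, 0, 2)
    t0
  })
  spec <- model_spec(trait_spec("resp", "gaussian", "age_months",
                                random = character(0), resid_fixed = 4))
  fit <- fit_model(tab, spec, mcmc_config(6000, 1000, 1, seed = 5), quiet = TRUE)
  X <- cbind(1, tab$age_months)
  bhat <- drop(solve(crossprod(X), crossprod(X, tab$value)))
  Vb <- 4 * solve(crossprod(X))
  post_mean <- colMeans(fit$samples[, 1:2])
  post_sd <- apply(fit$samples[, 1:2], 2, sd)
  expect_lt(max(abs(post_mean - bhat) / sqrt(diag(Vb))), 0.1)
  expect_lt(max(abs(post_sd / sqrt(diag(Vb)) - 1)), 0.1)
})

test_that("balanced one-way variance components match the moments oracle", {
  tab <- one_way_table(100, 4, var_mother = 2, var_resid = 2, seed = 8)
  spec <- model_spec(trait_spec("resp", "gaussian", character(0), random = "mother"))
  fit <- fit_model(tab, spec, mcmc_config(8000, 2000, 3, seed = 2), quiet = TRUE)
  oracle <- anova_components(tab$value, tab$mother_id)
  vm <- fit$samples[, "G.motherCov[resp,resp]"]
  vr <- fit$samples[, "R.resid[resp,resp]"]
  expect_lt(abs(mean(vm) - oracle[["var_mother"]]) / oracle[["var_mother"]], 0.2)
  expect_lt(abs(mean(vr) - oracle[["var_resid"]]) / oracle[["var_resid"]], 0.2)
  hm <- hpd_interval(vm); hr <- hpd_interval(vr)
  expect_true(hm[1] <= 2 && 2 <= hm[2])
  expect_true(hr[1] <= 2 && 2 <= hr[2])
})

test_that("covariance Gibbs draw honours the mask and the inverse-Wishart mean", {
  C <- matrix(c(4, 1, 0, 1, 3, 0, 0, 0, 2), 3, 3)
  mask <- matrix(FALSE, 3, 3); mask[1:2, 3] <- mask[3, 1:2] <- TRUE
  withr::with_seed(1, {
    draw <- gibbs_update_covariance(C * 50, 50, list(V = diag(3), nu = 3.002), mask)
  })
  expect_identical(draw[1, 3], 0); expect_identical(draw[3, 2], 0)
  expect_gt(draw[3, 3], 0)
  expect_error(gibbs_update_covariance(C, 10, list(V = diag(3), nu = 1), NULL),
               "degrees of freedom")

  # prior washes out: mean of draws -> crossprod / n_levels
  Ctrue <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  n <- 2000
  withr::with_seed(2, {
    draws <- replicate(4000, gibbs_update_covariance(Ctrue * n, n,
                                                     list(V = diag(2), nu = 2.002)))
  })
  m <- apply(draws, c(1, 2), mean)
  expect_lt(max(abs(m - Ctrue) / Ctrue[1, 1]), 0.02)

  # 1x1 case is scaled inverse-chi-square: IW(1, 3) has 1/x ~ chisq(3)
  withr::with_seed(3, {
    x <- replicate(10000, gibbs_update_covariance(matrix(0), 0,
                                                  list(V = matrix(1), nu = 3))[1, 1])
  })
  ks <- stats::ks.test(x, function(q) 1 - pchisq(1 / q, 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("latent liability updates satisfy their conditional distribution", {
  # near-degenerate limit: strong positive predictor with outcome 1
  withr::with_seed(4, {
    l <- rep(0, 1000)
    for (i in 1:30) l <- as.numeric(update_binary_latents(l, 10, rep(1, 1000), tuning = 2))
    expect_gt(mean(l > 0), 0.99)
  })
  # symmetry: predictor 0 with balanced outcomes -> mean near 0
  withr::with_seed(5, {
    l <- rep(0, 2000); y <- rep(c(0, 1), 1000); acc <- 0
    for (i in 1:200) l <- as.numeric(update_binary_latents(l, 0, y, tuning = 2))
    expect_lt(abs(mean(l)), 0.1)
  })
  # single-site long-run distribution matches a rejection sampler
  withr::with_seed(6, {
    l <- 0; draws <- numeric(20000)
    for (i in 1:20000) {
      l <- as.numeric(update_binary_latents(l, 0.5, 1, tuning = 2.5))
      draws[i] <- l
    }
    rej <- c()
    while (length(rej) < 4000) {
      z <- rnorm(10000, 0.5, 1)
      rej <- c(rej, z[runif(10000) < plogis(z)])
    }
    ks <- suppressWarnings(stats::ks.test(draws[seq(1, 20000, 5)], rej))
    expect_gt(ks$p.value, 0.01)
  })
  expect_error(update_binary_latents(0, 0, 2), "0/1")
})

test_that("effective sample size behaves on iid, antithetic and AR(1) chains", {
  withr::with_seed(7, {
    expect_true(dplyr::between(effective_sample_size(rnorm(1000)), 700, 1300))
    ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 10000))
    ess <- effective_sample_size(ar)
    expect_lt(abs(ess - 526) / 526, 0.3)
  })
  alt <- rep(c(1, -1), 500)
  expect_warning(ess_alt <- effective_sample_size(alt), "capping")
  expect_equal(ess_alt, 1000)
  expect_warning(ess_const <- effective_sample_size(rep(2, 100)), "constant")
  expect_equal(ess_const, 0)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("structural constraints hold exactly in every retained sample", {
  sim <- simulate_dataset(sim_config(n_mothers = 40, n_extra_females = 0, seed = 13,
                                     traits = c("py_movement", "subadult_survival")))
  spec <- model_spec(
    traits = list(
      trait_spec("py_movement", "gaussian", c("sex"), random = "mother"),
      trait_spec("subadult_survival", "binary_logit", c("sex"), random = "mother")
    ),
    resid_groups = list(c("py_movement", "subadult_survival"))
  )
  fit <- fit_model(sim$table, spec, mcmc_config(1500, 500, 2, seed = 6), quiet = TRUE)
  S <- fit$samples
  expect_true(all(S[, "R.resid[subadult_survival,subadult_survival]"] == 1))
  # the 2x2 mother covariance is PSD in every sample
  dets <- S[, "G.motherCov[py_movement,py_movement]"] *
    S[, "G.motherCov[subadult_survival,subadult_survival]"] -
    S[, "G.motherCov[py_movement,subadult_survival]"]^2
  expect_true(all(dets > 0))
  # the within-group residual matrix stays PSD with the binary variance pinned
  rdet <- S[, "R.resid[py_movement,py_movement]"] * 1 -
    S[, "R.resid[py_movement,subadult_survival]"]^2
  expect_true(all(rdet > 0))
})

test_that("masked residual covariances are exactly zero in every sample", {
  sim <- simulate_dataset(bivariate_fid_config(seed = 31, n_mothers = 30, n_extra = 5))
  fit <- fit_model(sim$table, model_spec_bivariate_fid(sim$table),
                   mcmc_config(1000, 300, 2, seed = 1), quiet = TRUE)
  expect_true(all(fit$samples[, "R.resid[subadult_fid,adult_female_fid]"] == 0))
  expect_true(all(fit$samples[, "G.offspringVar[subadult_fid]"] > 0))
})

test_that("permuting trait order permutes the posterior matrices correspondingly", {
  sim <- simulate_dataset(bivariate_fid_config(seed = 17, n_mothers = 40, n_extra = 5,
                                               offspring_mean = 1.6))
  fe <- list(subadult_fid = c("sex"), adult_female_fid = c("observer_id"))
  mk <- function(order12) {
    tr <- list(
      trait_spec("subadult_fid", "gaussian", fe$subadult_fid, random = "mother"),
      trait_spec("adult_female_fid", "gaussian", fe$adult_female_fid, random = "mother")
    )
    model_spec(if (order12) tr else rev(tr))
  }
  f1 <- fit_model(sim$table, mk(TRUE), mcmc_config(3000, 1000, 2, seed = 4), quiet = TRUE)
  f2 <- fit_model(sim$table, mk(FALSE), mcmc_config(3000, 1000, 2, seed = 9), quiet = TRUE)
  # the cross-trait covariance keeps its trait labels (order within the
  # bracket follows the model declaration) and agrees across orderings
  p1 <- "G.motherCov[subadult_fid,adult_female_fid]"
  p2 <- "G.motherCov[adult_female_fid,subadult_fid]"
  expect_true(p1 %in% colnames(f1$samples))
  expect_false(p2 %in% colnames(f1$samples))
  expect_true(p2 %in% colnames(f2$samples))
  expect_lt(abs(mean(f1$samples[, p1]) - mean(f2$samples[, p2])),
            3 * (sd(f1$samples[, p1]) + sd(f2$samples[, p2])) / sqrt(50))
  for (p in c("G.motherCov[subadult_fid,subadult_fid]",
              "G.motherCov[adult_female_fid,adult_female_fid]")) {
    expect_lt(abs(mean(f1$samples[, p]) - mean(f2$samples[, p])),
              3 * (sd(f1$samples[, p]) + sd(f2$samples[, p])) / sqrt(50))
  }
})

test_that("model data validation errors are informative", {
  tab <- one_way_table(5, 2, 1, 1)
  spec <- model_spec(trait_spec("resp", "gaussian", "no_such_column",
                                random = "mother"))
  expect_error(fit_model(tab, spec), "no_such_column")
  spec2 <- model_spec(trait_spec("absent_trait", "gaussian", character(0)))
  expect_error(fit_model(tab, spec2), "absent_trait")
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})
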