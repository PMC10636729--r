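test_that("latent repeatability follows the variance ratio", {
  expect_equal(latent_repeatability(0, 1), 0)
  expect_equal(latent_repeatability(1, 1), 0.5)
  expect_equal(round(latent_repeatability(1.54, 1), 4), 0.6063)
  expect_error(latent_repeatability(-1, 1), "var_mother")
  expect_error(latent_repeatability(1, 0), "var_residual")
})

test_that("data-scale components are exact in the symmetric null case", {
  dc <- data_scale_components(0, 1, latent_means = 0)
  expect_equal(dc$expected_phenotype, 0.5, tolerance = 1e-10)
  expect_equal(dc$var_mother_data, 0, tolerance = 1e-12)
  expect_equal(dc$maternal_repeatability_data, 0, tolerance = 1e-12)
  expect_error(data_scale_components(1, 1, latent_means = Inf), "finite")
  expect_error(data_scale_components(1, 1, 0, quadrature_order = 11), "quadrature_order")
})

test_that("components always sum to the Bernoulli total and are stable in the order", {
  grid <- expand.grid(vm = c(0.1, 0.5, 1.54, 3), mu = c(-2, 0, 1))
  for (i in seq_len(nrow(grid))) {
    dc <- data_scale_components(grid$vm[i], 1, grid$mu[i], quadrature_order = 41)
    expect_lt(abs(dc$var_mother_data + dc$var_residual_data + dc$var_binomial -
                    dc$total), 1e-6)
    dc2 <- data_scale_components(grid$vm[i], 1, grid$mu[i], quadrature_order = 82)
    expect_lt(abs(dc$maternal_repeatability_data - dc2$maternal_repeatability_data),
              1e-6)
  }
})

test_that("data-scale repeatability never exceeds the latent-scale ratio", {
  for (vm in c(0.1, 0.5, 1, 2, 5)) {
    for (mu in -2:2) {
      dc <- data_scale_components(vm, 1, mu)
      expect_lte(dc$maternal_repeatability_data, latent_repeatability(vm, 1))
    }
  }
})

test_that("quadrature matches the Monte Carlo oracle within its error", {
  withr::with_seed(20, {
    for (i in 1:4) {
      vm <- runif(1, 0.2, 3)
      mu <- rnorm(3, 0.5, 1)
      dc <- data_scale_components(vm, 1, mu)
      mc <- mc_oracle_data_scale(vm, 1, mu, n_draws = 2e5, seed = 100 + i)
      for (q in names(mc$estimate)) {
        expect_lt(abs(mc$estimate[[q]] - dc[[if (q == "total") "total" else q]]),
                  3 * max(mc$se[[q]], 1e-6))
      }
      # binary variance identity on the simulated outcomes
      expect_lt(abs(mc$var_outcome - mc$estimate[["total"]]), 0.01)
    }
  })
  expect_error(mc_oracle_data_scale(1, 1, 0, n_draws = 100), "n_draws")
  mc0 <- mc_oracle_data_scale(0, 1, 0, n_draws = 1e5, seed = 5)
  expect_lt(abs(mc0$estimate[["maternal_repeatability_data"]]),
            3 * mc0$se[["maternal_repeatability_data"]])
})

test_that("naming in data_scale_components matches the oracle's component names", {
  dc <- data_scale_components(1, 1, 0)
  mc <- mc_oracle_data_scale(1, 1, 0, n_draws = 1e5, seed = 1)
  expect_true(all(setdiff(names(mc$estimate), "total") %in% names(dc)))
})
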