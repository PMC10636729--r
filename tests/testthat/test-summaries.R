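constant_samples <- function(values, n = 100) {
  S <- matrix(rep(values, each = n), nrow = n)
  colnames(S) <- names(values)
  S
}

test_that("posterior mode recovers known density modes", {
  expect_equal(posterior_mode(rep(3.7, 60)), 3.7)
  withr::with_seed(1, {
    expect_lt(abs(posterior_mode(rnorm(1e5, 3, 1)) - 3), 0.1)
    x <- rlnorm(1e5, 0, 1)
    m <- posterior_mode(x)
    expect_lt(abs(m - exp(-1)), 0.05)
    expect_lt(m, mean(x))  # clearly below the mean 1.65 for this skew
  })
  expect_error(posterior_mode(1:10), "at least 50")
})

test_that("HPD interval is the shortest contiguous sample window", {
  h <- hpd_interval(1:100, 0.95)
  expect_equal(h[["high"]] - h[["low"]], 95)
  expect_equal(hpd_interval(rep(2, 60))[["high"]] - hpd_interval(rep(2, 60))[["low"]], 0)
  withr::with_seed(2, {
    u <- runif(1e6)
    h <- hpd_interval(u, 0.95)
    expect_true(h[["high"]] - h[["low"]] > 0.94 && h[["high"]] - h[["low"]] < 0.96)
  })
  # exhaustive check of the shortest-window rule on a small skewed sample
  withr::with_seed(3, {
    x <- sort(rexp(80))
    h <- hpd_interval(x, 0.9)
    m <- ceiling(0.9 * 80)
    widths <- x[(m + 1):80] - x[1:(80 - m)]
    expect_equal(h[["high"]] - h[["low"]], min(widths))
  })
  samp <- rnorm(100)
  h <- hpd_interval(samp)
  expect_gte(h[["low"]], min(samp)); expect_lte(h[["high"]], max(samp))
  expect_error(hpd_interval(rnorm(100), prob = 1.2), "prob")
})

test_that("pMCMC follows the two-sided sign rule with a 1/N floor", {
  expect_equal(pmcmc(rep(1, 1000) + runif(1000)), 0.001)
  expect_equal(pmcmc(c(rep(-1, 500), rep(1, 500))), 1)
  withr::with_seed(4, {
    expect_lt(abs(pmcmc(rnorm(1e5, 1.96, 1)) - 0.05), 0.01)
  })
})

test_that("variance decomposition reproduces worked point-value examples", {
  S <- constant_samples(c(
    "G.motherCov[subadult_fid,subadult_fid]" = 4.97,
    "G.offspringVar[subadult_fid]" = 3.61,
    "R.resid[subadult_fid,subadult_fid]" = 8.11
  ))
  d <- decompose_variance(S, "subadult_fid")
  get <- function(q) d$posterior_mode[d$quantity == q]
  expect_equal(round(get("individual_repeatability"), 4), 0.2163)  # 3.61 / 16.69
  expect_equal(round(get("total_repeatability"), 4), 0.5141)       # 8.58 / 16.69
  expect_equal(get("maternal_proportion_of_total"), 4.97 / 8.58, tolerance = 1e-10)

  # equal components: symmetric thirds
  Se <- constant_samples(c(
    "G.motherCov[t,t]" = 2, "G.offspringVar[t]" = 2, "R.resid[t,t]" = 2
  ))
  de <- decompose_variance(Se, "t")
  gete <- function(q) de$posterior_mode[de$quantity == q]
  expect_equal(gete("maternal_repeatability"), 1 / 3, tolerance = 1e-12)
  expect_equal(gete("individual_repeatability"), 1 / 3, tolerance = 1e-12)
  expect_equal(gete("total_repeatability"), 2 / 3, tolerance = 1e-12)
  expect_equal(gete("maternal_proportion_of_total"), 1 / 2, tolerance = 1e-12)
  expect_error(decompose_variance(Se, "unknown_trait"), "mother-level")
})

test_that("proportions sum to one for every posterior sample", {
  withr::with_seed(5, {
    S <- cbind(rlnorm(200), rlnorm(200), rlnorm(200))
    colnames(S) <- c("G.motherCov[t,t]", "G.offspringVar[t]", "R.resid[t,t]")
    d <- decompose_variance(S, "t")
    dr <- attr(d, "draws")
    sums <- dr$maternal_repeatability + dr$individual_repeatability +
      dr$residual_proportion
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(dr$total_repeatability >= 0 & dr$total_repeatability <= 1))
  })
})

test_that("upper-limit heritability doubles the mother-offspring regression", {
  S <- constant_samples(c(
    "G.motherCov[subadult_fid,adult_female_fid]" = 4.14,
    "G.motherCov[adult_female_fid,adult_female_fid]" = 4.78
  ))
  h <- upper_limit_h2(S)
  expect_equal(round(h$posterior_mode, 2), 1.73)
  S0 <- constant_samples(c(
    "G.motherCov[subadult_fid,adult_female_fid]" = 0,
    "G.motherCov[adult_female_fid,adult_female_fid]" = 2
  ))
  expect_equal(upper_limit_h2(S0)$posterior_mode, 0)
  Sb <- constant_samples(c(
    "G.motherCov[subadult_fid,adult_female_fid]" = 1.5,
    "G.motherCov[adult_female_fid,adult_female_fid]" = 3
  ))
  expect_equal(upper_limit_h2(Sb)$posterior_mode, 1)  # cov = var / 2
  # samples with non-positive maternal variance are excluded with a warning
  Sneg <- Sb
  Sneg[1:3, 2] <- -1
  expect_warning(hn <- upper_limit_h2(Sneg), "excluded")
  expect_equal(hn$n_excluded, 3L)
})
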