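# maternalvar

Partitioning variance in early-life behaviour and survival between
mothers, individuals and residual noise, by Gibbs-sampled multi-trait
Bayesian mixed models.

## The problem

In wild populations, offspring of the same mother resemble each other —
through shared genes and through everything the mother does. For
behavioural ecologists this *maternal repeatability* (between-mother
variance over total variance) measures how much of juvenile "personality"
is set by maternal identity, and the mother–offspring covariance bounds how
heritable the behaviour can be. The motivating setting is a marsupial-type
field study: pouch-young activity scored over 8 binary handling stages,
flight initiation distance (FID) measured repeatedly on subadults and adult
females, and binary survival to weaning.

`maternalvar` is for quantitative ecologists who want this analysis as
tested, reusable code: a multi-trait GLMM Gibbs sampler written for exactly
this model class, the latent-to-data-scale conversion for the binary trait,
the repeatability decompositions, and a synthetic-data generator with known
ground truth so every stage is verifiable without any field data.

## The model

For trait *t* on observation *i*,

    y_ti = x_ti' beta_t + u_{m(i),t} + v_{o(i),t} + e_ti

with mother-level effect vectors **u**_m ~ N(0, **G**) (unstructured
covariance across all traits), optional individual-level effects *v* for
repeated-measures traits, and residuals that covary freely within a
residual group but are fixed to exactly zero across groups (traits measured
on disjoint units). Binary traits enter via a latent logit liability with
residual variance fixed at 1. Covariance blocks carry inverse-Wishart
priors (V = I, nu = dim + 0.002); fixed effects are flat.

Reported quantities, each computed per posterior sample and summarised by
the posterior mode and 95% highest-posterior-density interval:

* maternal repeatability `var_Mother / total`, individual repeatability
  `var_Offspring / total`, residual proportion;
* total repeatability `(var_Mother + var_Offspring) / total` and the
  maternal proportion of it `var_Mother / (var_Mother + var_Offspring)`;
* data-scale repeatability of the binary trait, with the binomial sampling
  variance `E[p(1-p)]` in the denominator;
* the upper-limit heritability `2 * cov(Mother, Offspring) / var_Mother`
  from the mother-offspring FID covariance.

## Worked example

Simulate a study-sized dataset under known truth (mother-level FID
covariance matrix [[4.97, 4.14], [4.14, 4.78]], offspring variance 3.61,
residuals 8.11/8.50), then fit the bivariate repeated-measures FID model:

```r
library(maternalvar)

sim <- simulate_dataset(sim_config(seed = 1))
fit <- fit_model(sim$table, model_spec_bivariate_fid(sim$table),
                 mcmc_config(n_iter = 20000, burn_in = 5000, thin = 10, seed = 1))

covariance_summary(fit) |> dplyr::filter(grepl("^G", parameter_name))
#> # A tibble: 4 x 5
#>   parameter_name                                 posterior_mode hpd_low hpd_high    pMCMC
#> 1 G.motherCov[subadult_fid,subadult_fid]                   4.63    2.74     7.30 0.000667
#> 2 G.motherCov[subadult_fid,adult_female_fid]               4.81    3.26     6.45 0.000667
#> 3 G.motherCov[adult_female_fid,adult_female_fid]           5.70    4.39     7.50 0.000667
#> 4 G.offspringVar[subadult_fid]                             3.32    1.84     5.01 0.000667

decompose_variance(fit, "subadult_fid")
#> # A tibble: 5 x 5
#>   trait        quantity                     posterior_mode hpd_low hpd_high
#> 1 subadult_fid maternal_repeatability                0.305   0.193    0.411
#> 2 subadult_fid residual_proportion                   0.504   0.419    0.574
#> 3 subadult_fid individual_repeatability              0.209   0.120    0.301
#> 4 subadult_fid total_repeatability                   0.496   0.426    0.581
#> 5 subadult_fid maternal_proportion_of_total          0.578   0.405    0.760

upper_limit_h2(fit)
#> # A tibble: 1 x 4
#>   posterior_mode hpd_low hpd_high n_excluded
#> 1           1.63    1.22     2.11          0
```

Reading the output: about half the variance in subadult FID is repeatable
(total repeatability 0.50), and more than half of that repeatable part
(0.58) traces to differences between mothers rather than between
individual offspring — the generating ratios were 0.51 and 0.58. The
posterior modes of the mother-level components sit near their generating
values, and the upper-limit heritability interval covers the generating
value 2 x 4.14 / 4.78 = 1.73; a value above 1 diagnoses inflation of the
mother-offspring covariance by shared-environment effects.

`run_full_analysis()` runs the whole pipeline (the four-trait model with
averaged subadult FID, the bivariate FID model, the data-scale conversion
of survival components, and the adoption regression when cross-fostered
offspring are present); `write_report_json()` serialises the result. A
thin command-line wrapper lives in `inst/cli/maternalvar` with `simulate`,
`fit`, `summarize` and `report` subcommands.

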