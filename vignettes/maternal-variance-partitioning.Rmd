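---
title: "Partitioning behavioural and survival variance between mothers, individuals and noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning behavioural and survival variance between mothers, individuals and noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternalvar)
```

## The scientific question

In wild mammal populations, offspring of the same mother tend to resemble
each other — through the genes they share, and through everything the mother
does and provides. For behavioural traits this sibling similarity is
interesting twice over: it measures how much of "personality" (repeatable
between-individual differences) is already set by maternal identity, and it
bounds how heritable the behaviour can be. `maternalvar` implements the
statistical machinery for this question in the setting of a marsupial-type
study design: offspring behaviour scored while still in the pouch, flight
initiation distance (FID, the distance at which an animal flees an
approaching human) measured repeatedly on subadults and on adult females,
and survival to weaning recorded as a binary outcome.

The quantities of interest are ratios of variance components:

* **maternal repeatability** of a trait,
  $R_{\mathrm{mat}} = \sigma^2_M / \sigma^2_{\mathrm{total}}$, the share of
  phenotypic variance attributable to differences between mothers
  (between-mother variance implies within-mother, i.e. sibling, covariance);
* **individual repeatability**,
  $R_{\mathrm{ind}} = \sigma^2_O / \sigma^2_{\mathrm{total}}$, consistent
  differences between individual offspring beyond the maternal level;
* **total repeatability** of subadult FID,
  $(\sigma^2_M + \sigma^2_O) / (\sigma^2_M + \sigma^2_O + \sigma^2_E)$, and
  the **maternal proportion of total repeatability**,
  $\sigma^2_M / (\sigma^2_M + \sigma^2_O)$;
* an **upper-limit heritability** from the mother–offspring covariance,
  $h^2_{\mathrm{upper}} = 2\,\mathrm{cov}(M_{\mathrm{off}},
  M_{\mathrm{mum}}) / \sigma^2_{M,\mathrm{mum}}$ — twice the
  mother–offspring regression slope, inflated by any shared-environment
  effects (values above 1 are reported as-is, since they diagnose exactly
  that inflation).

## The model

`fit_model()` fits a multi-trait generalized linear mixed model by Gibbs
sampling. For trait $t$ on observation $i$,

$$y_{ti} = \mathbf{x}_{ti}'\boldsymbol\beta_t + u_{m(i),t} + v_{o(i),t} + e_{ti},$$

where $\mathbf u_m \sim \mathcal N(\mathbf 0, \mathbf G)$ is a mother-level
effect vector with *unstructured* covariance across all traits (its
diagonal gives the maternal variances, its off-diagonal elements the
maternal-level cross-trait covariances, including the mother–offspring FID
covariance when the mother's own FID is one of the traits and each female's
adult trials carry her own identity as the grouping factor);
$v$ is an optional scalar individual-level effect for repeated-measures
traits; and residuals are multivariate normal within *residual groups*.
Traits measured on the same observational unit (the three offspring traits,
one record each per offspring) share a free residual covariance; traits
measured on disjoint units (adult-female FID versus the offspring traits)
have that covariance fixed to exactly zero, because no unit ever expresses
both.

A binary trait (survival) enters through a latent logit liability
$\ell_i$ with $y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\ell_i))$
and liability residual variance fixed at 1 — a Bernoulli outcome carries no
information about a residual scale, so the latent scale is pinned by
convention and all latent variances are interpreted relative to it.

### Priors

Fixed effects receive improper flat priors. Every free covariance block
(the mother-level matrix $\mathbf G$, each residual block, each
individual-level variance) has an inverse-Wishart prior with scale matrix
$V = I$ and degrees of freedom $\nu = p + 0.002$ for a $p$-dimensional
block — proper but weakly informative, a conventional choice for this model
class. All prior hyperparameters are arguments of `model_spec()`.

### The sampler

All updates are blocked Gibbs draws with one Metropolis ingredient:

* fixed effects: a joint conjugate normal draw per residual group
  (generalized least squares given the current random effects and residual
  covariance);
* mother effect vectors: conjugate multivariate normal draws, vectorised
  across mothers (closed-form $2\times2$ algebra when at most two traits
  carry a mother term; shared Cholesky factors per observation-count
  pattern otherwise);
* covariance blocks: conditional inverse-Wishart draws
  (`gibbs_update_covariance()`);
* binary liabilities: single-site random-walk Metropolis
  (`update_binary_latents()`), whose conditional target is
  $\mathcal N(\ell \mid \eta, \sigma^2_c)\,\mathrm{Bernoulli}(y \mid
  \mathrm{logit}^{-1}(\ell))$. The proposal scale adapts toward a 0.44
  acceptance rate during burn-in only and is frozen afterwards, so detailed
  balance holds over the retained chain.

Two constraints require care. First, the residual block containing the
binary trait must keep its liability variance at exactly 1 while its
covariances with Gaussian traits stay free. The block is parameterised as
$e_{\mathrm G} = \boldsymbol\beta_c e_{\mathrm b} + \boldsymbol\delta$ with
$\boldsymbol\delta \sim \mathcal N(\mathbf 0, \Sigma_\delta)$, which spans
exactly the set of covariance matrices with the binary diagonal pinned at
1; $\boldsymbol\beta_c$ gets a conjugate normal draw and $\Sigma_\delta$ an
inverse-Wishart draw. Second, a unit may lack some traits (an offspring
with survival but no pouch score). Those cells' latent residuals are drawn
from their conditional normal each sweep, which integrates them out — the
posterior for everything else is identical to a model that simply omits
those likelihood contributions, and no observed data are ever imputed.

### Run lengths

The sampler defaults (`mcmc_config()`: 20\,000 iterations, 5\,000 burn-in,
thinning 10) are sized for simulation studies and interactive work on
designs of one-to-two hundred mothers; a full-length analysis in the style
of field studies of this kind (1.3 million iterations, 300\,000 burn-in,
thinning 1\,000) is a configuration choice:

```{r, eval = FALSE}
mcmc_config(n_iter = 1300e3, burn_in = 300e3, thin = 1e3, seed = 1)
```

`fit_model()` computes an autocorrelation-based effective sample size
(`effective_sample_size()`, Geyer's initial-sequence estimator) for every
(co)variance parameter and warns below 200.

## Latent versus data scale for the binary trait

Latent-scale maternal repeatability of survival is
$\sigma^2_M / (\sigma^2_M + 1)$. On the observed 0/1 scale the total
variance is $\bar p(1-\bar p)$ and contains an irreducible *binomial
sampling variance* $E[p(1-p)]$, so the data-scale ratio

$$R_{\mathrm{mat}}^{\mathrm{data}} =
  \frac{\mathrm{Var}_m\!\left(E[p \mid m]\right)}
       {\mathrm{Var}_m\!\left(E[p \mid m]\right) + E_m[\mathrm{Var}(p \mid m)] + E[p(1-p)]}$$

is always far smaller than the latent one. `data_scale_components()`
computes all terms by Gauss–Hermite quadrature (default order 41; results
are stable to $10^{-6}$ under order doubling, and the three components sum
to $\bar p(1-\bar p)$ exactly up to quadrature error);
`mc_oracle_data_scale()` is an independent brute-force simulator with
Monte Carlo standard errors used to cross-validate it. One convention
deserves note: denominators mixing the latent residual (fixed at 1) with
data-scale components appear in parts of the literature; this package
computes the fully data-scale decomposition above, in the spirit of the
`QGicc` back-transformation of the QGglmm tradition. The latent means are
taken as the per-observation fixed-effect predictors of each posterior
sample (`data_scale_posterior()`), with an intercept-only mode available by
passing a single value.

Conversions are applied *per posterior sample* and then summarised — the
package never forms ratios of posterior summaries. Point-value ratios
(e.g. `3.61 / (4.97 + 3.61 + 8.11)`) and posterior modes of per-sample
ratios differ slightly; both are meaningful, and the test-suite worked
examples use the former while the pipeline reports the latter.

## Posterior summaries

(Co)variance parameters and ratios are summarised by the **posterior
mode** — the peak of a Gaussian-kernel density estimate with Silverman's
rule-of-thumb bandwidth on a 2\,048-point grid spanning the sample range
(modes of skewed variance posteriors sit well below means, which is why
this estimator is conventional here); fixed effects by posterior means. All
intervals are **95% highest posterior density** intervals: the shortest
window of sorted samples containing $\lceil 0.95 N \rceil$ draws.
**pMCMC** is $2\min(\Pr(>0), \Pr(<0))$, floored at $1/N$ since a finite
chain cannot certify an exact zero.

## The synthetic-data generator

`simulate_dataset()` exists so that every stage of the pipeline is testable
with known ground truth. Its defaults emulate the structure of a
wild-population study of this kind:

* 111 mothers with measured offspring plus 45 additional adult females with
  FID trials only (156 females in total); 1–3 offspring per mother
  (truncated Poisson, mean 1.6);
* a 0–1 pouch-young movement score built from 8 independent Bernoulli
  handling-stage indicators (6 in an abbreviated protocol), driven by a
  latent logit stage propensity with mother-level variance 1.2, residual
  0.8 and intercept $\mathrm{logit}(0.47)$ — the score is generated on the
  propensity scale because that is how a sum of stage indicators arises,
  even though the analysis models the score as Gaussian;
* repeated FID trials: 1–10 per subadult (mean 4.6) and 1–14 per adult
  female (mean 5.6); Gaussian in metres with mother-level (co)variances
  4.97 / 4.14 / 4.78, offspring-level variance 3.61 and residuals
  8.11 / 8.50 — values of the magnitude reported for repeated-measures FID
  in such populations (the generating 4-trait mother covariance must be
  positive semidefinite, which constrains the FID block to these
  repeated-measures values);
* binary survival through a latent logit liability with mother-level
  variance 1.54, unit residual and intercept 0.97, giving roughly 67%
  survival;
* covariates as in field protocols: sex (Bernoulli 0.5), year, an east–west
  GPS coordinate (uniform over 2 km), group size (uniform 1–6), companion
  class with frequencies 44.3 / 20.9 / 6.6 / 18.7 / 9.4% for adult females
  and mother-present in 31.4% of subadult trials, test number, days since
  the previous test (with the first trial's value set to the sentinel 500,
  larger than any real gap), and a two-level observer factor for 9% of
  adult trials.

FID values are generated as (possibly negative) Gaussians by default,
matching the Gaussian analysis model; truncation at zero is available but
off. `assign_adoptions()` swaps rearing mothers reciprocally to emulate the
rare cross-fostering events that let a mother–offspring regression contrast
rearing against biological mothers.

What the generator deliberately does **not** emulate: spatial structure
beyond the single east–west coordinate, behavioural mechanism (habituation
is only a linear test-number effect), overlapping-but-unequal trait
coverage of individuals (records are complete by default), and
measurement-protocol drift. Parameter-recovery results on these synthetic
data therefore show that the estimator works under the model's own
assumptions at realistic sizes — not that any particular field dataset
satisfies those assumptions.

## Numerical choices and degenerate inputs

* Cholesky factorisations with an eigenvalue fallback for semidefinite
  generating covariances.
* `hpd_interval()` returns a zero-width interval for constant samples;
  `posterior_mode()` returns the constant.
* A design with every mother represented by a single observation leaves
  mother and residual variance separated only by the prior; the sampler
  runs (the posterior is proper) but intervals are wide — by design, not
  error.
* Liability proposal scales are clamped to [0.1, 20].
* `read_observations()` validates score multiples, binary values and the
  one-biological-mother invariant, reporting CSV line numbers.

## Limitations

No pedigree ("animal model") relatedness structure — mother-level variance
mixes additive-genetic and maternal-environment effects, which is exactly
why the heritability estimate is only an upper bound. Single-chain
sampling (replicate seeds substitute for multi-chain diagnostics). Logit
link only for the binary trait. The adoption regression uses per-animal
mean FIDs; with the handful of adoptions such populations offer, its
intervals are rightly enormous.
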