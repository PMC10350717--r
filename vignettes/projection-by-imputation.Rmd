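---
title: "Projecting prevalences by multiple imputation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting prevalences by multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevproj)
```

## The model

The package projects the prevalence of binary risk factors from repeated
cross-sectional surveys by treating future survey waves as missing data.
Three ingredients define the procedure.

**Pseudo-samples.** For a projection year, a sample of pseudo-individuals
is appended to the data with survey year, sex and single-year age fixed
and everything else missing. Its (sex, age) composition matches the
population forecast *exactly*, by largest-remainder (Hamilton)
integerization of the forecast shares: cells are ordered by (sex level,
age), fractional seats go to the largest remainders, remainder ties to
the lowest-index cell. Exact matching was chosen over multinomial
sampling so that projections are not perturbed by extra demographic
noise; the sampling alternative would add variability that the pooling
step could not distinguish from parameter uncertainty. Ages are integer
years without within-year jitter, but age enters all models as a
continuous covariate.

**Fully conditional specification.** Each incomplete variable `v` has a
conditional model given all other variables. For each of `m` datasets,
missing cells are initialized by uniform draws from the variable's
observed values, then for a fixed number of cycles each variable is
revisited: its model is refit on the records where `v` was *originally
observed*, using the current completed values of all predictors, and all
originally missing cells are redrawn. Observed cells are never modified.
The visit order is ascending count of missing values (ties in schema
order), which stabilizes the chains by imputing the least-missing
variables first.

Binary variables use a "proper" logistic imputer: after a
ridge-stabilized fit, parameters are drawn from the asymptotic normal
posterior approximation `MVN(beta_hat, V_hat)` and imputations are
Bernoulli draws at the resulting probabilities, so between-imputation
variance reflects parameter uncertainty. Categorical variables use a
bootstrap multinomial imputer (refit on a resample, draw from fitted
probabilities); the bootstrap plays the role of the parameter draw
because a parametric posterior for multinomial fits is harder to
stabilize.

**Rubin's rules.** Per dataset, a cell prevalence `q_i` gets the Wald
within-variance `w_i = q_i (1 - q_i) / n`. Pooling gives
`Qbar = mean(q_i)`, `Wbar = mean(w_i)`, between-variance `B`,
total variance `T = Wbar + (1 + 1/m) B`, degrees of freedom
`nu = (m - 1)(1 + Wbar / ((1 + 1/m) B))^2`, and a t interval truncated
to [0, 1]; `B = 0` falls back to the normal quantile. Pooling is done on
the proportion scale, matching how prevalence trends are usually plotted
and combined; a logit-scale alternative would behave better for
prevalences very near 0 or 1 but is not the default because the
indicators of interest live comfortably inside the unit interval. The
classical large-sample degrees of freedom are used rather than the
Barnard–Rubin small-sample adjustment, since completed pseudo-samples
are large by construction.

## Calendar time and extrapolation

Projection is extrapolation in calendar time, so the year term deserves
care. Year can enter models linearly or through a restricted cubic
spline: with knots `t1 < ... < tk`, the basis is the linear term plus
`k - 2` restricted truncated-power terms, each zero below `t1`, twice
continuously differentiable, and *exactly linear* above `tk`. Knots are
placed at Harrell's default quantiles of the distinct observed values
(0.10 / 0.50 / 0.90 for three knots) and are **frozen at the observed
survey years** before any pseudo-wave is seen. Future years therefore
lie in the spline's linear tail: the spline captures curvature inside
the observed period and extrapolates the terminal slope, which is the
behavior that makes spline-based projections sensible. The
`sensitivity_compare()` diagnostic runs the pipeline under linear and
spline year terms with a shared seed, because the two can diverge
substantially when the observed trend is curved — a sensitivity analysis
worth reporting alongside any projection.

Model structure (interactions, spline vs linear year) can be selected by
forward stepwise search under BIC (`k log n - 2 loglik`, lower better),
starting from main effects. A spline candidate *replaces* the linear
term of its variable so the two compete directly. The search space and
strategy are a package choice — candidate lists are declared by the user
or config — since any stepwise scheme is one of several defensible
options; the fitting set is the available-case set (outcome observed,
candidate predictors complete) because selection precedes imputation.
Whether interactions should enter before or after the spline decision is
equally open; candidates compete simultaneously here, which avoids
ordering the two kinds of terms by fiat.

## Numerical choices

* **Ridge default `1e-5`.** Small observed waves can separate; a tiny
  ridge keeps coefficients finite without visibly biasing estimates.
  The penalty is applied on an internally standardized scale
  (non-intercept design columns centered and scaled by fitting-sample
  mean/SD — which also conditions the optimization when covariates such
  as calendar years are far from zero); results are mapped back to the
  original scale. BIC uses the unpenalized log-likelihood at the lightly
  penalized estimate; at `1e-5` the discrepancy is negligible.
* **Newton with step-halving**, convergence on gradient/step below
  `1e-9`, error (with diagnostics) rather than silent non-convergence.
* **Posterior draws** symmetrize the covariance and tolerate eigenvalues
  down to `-1e-10` (clamped to zero); anything worse is an error.
* **Seeding.** The engine uses L'Ecuyer-CMRG substreams: the master seed
  spawns one independent stream per imputed dataset, so stacks are
  bit-reproducible, datasets are statistically independent, and the
  caller's RNG state is untouched.
* **Degenerate inputs.** One-level outcomes, empty cells, empty fitting
  sets, all-zero forecast cells and constant spline inputs are all
  explicit errors naming the offending variable or cell; a bootstrap
  resample that loses an outcome level is retried up to 10 times.
* **Printed percentages** round half-up to one decimal, matching the
  convention of published missingness tables.

## The synthetic-data generator

Real five-wave Finnish survey microdata are not public, so the package
generates data with the same *shape*: five waves 1997–2017 at the
published invited sizes (5000/4999/4000/4000/1635 men,
5000/5000/4000/4000/1542 women), ages uniform on 25–64, five areas,
three education levels, binary marital status, and three indicators
generated on the logit scale with sex, age-per-decade and
year-per-decade effects (optional curvature, interactions, education and
marital effects, and an abrupt single-wave level shock for
negative-control experiments). Item non-response is imposed missing at
random through logistic models in the *design variables only* — this is
enforced at configuration time, so MAR holds by construction. The
missingness logits were solved from the published table: the women-1997
obesity cell fixes the intercept (24.8%), the men-vs-women 1997 contrast
the male offset (32.1% vs 24.8%), and the men 1997→2012 change the
per-decade slope (32.1% → 48.5%). Indicator levels and trends are chosen
as plausible national values (obesity near 19% rising, smoking near 22%
falling with curvature, hypertension near 33% with a strong age
gradient). True prevalences implied by a configuration are computed by
exact enumeration over the discrete covariate space (integer age ×
education × marital × area), or by Monte-Carlo marginalization with
`1e5` draws when indicators come from the optional continuous BMI /
blood-pressure layer, which exists mainly to exercise the inclusive
clinical cutoffs (BMI ≥ 30; SBP ≥ 140 or DBP ≥ 90 or medication).

What the generator does *not* emulate: the real joint distribution of
the Finnish risk factors, unit versus item non-response structure
(masking is item-level; the published counts do not separate the two),
the flattening of missingness after 2012 (the calibrated model is linear
in year, so it overshoots the 2017 percentages slightly), survey
weights, and forecast uncertainty. Passing recovery tests therefore
demonstrates that the machinery is correct under MAR with a smooth
generating trend — not that any particular real-world projection is
right. The negative-control test makes the converse point deliberately:
an abrupt final-wave level drop is *not* captured, as a trend-following
method cannot anticipate structural breaks.

## Study sizes used by the tests and acceptance script

Simulation checks run at reduced scale chosen to keep the evidence sharp
while the suite stays quick: MCAR unbiasedness at n = 4000 with m = 10
over 50 seeded runs; projection coverage over 100 replicates of five
waves at 1000 invited per wave with two 3-year projection horizons,
m = 10 and 5 iterations; BIC recovery over 100 replicates at n = 5000;
the negative control over 30 replicates at 800 per wave. The acceptance
script runs the full published-scale data dimensions (all five waves,
10,000-person pseudo-samples, the 3177-person hold-out wave) with
m = 10 and 5 iterations; the published full-scale settings m = 50 and
10 iterations remain the package defaults of `fcs_impute()` and are what
an applied analysis should use.

## Known limitations

* Forecast uncertainty is not propagated: pseudo-sample margins are
  treated as fixed, so intervals understate uncertainty about the future
  population structure.
* Sampling variability of the observed waves enters only through the
  imputation models; no bootstrap over records is offered.
* No survey design weights, clustering or stratification.
* Only prevalences are pooled; model coefficients are not a supported
  estimand.
* Projections assume the modelled trends continue; the hold-out
  diagnostic can confirm consistency with a withheld wave but cannot
  validate the future.
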