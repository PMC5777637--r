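---
title: "Clustered mover-stayer multistate models for joint activity and damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered mover-stayer multistate models for joint activity and damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In psoriatic arthritis each of the 28 hand joints can be *active* (swollen or
painful, a reversible condition) and can become *damaged* (an irreversible,
clinically assessed state).  Patients are seen at clinic visits months apart,
so each joint's activity/damage process is a continuous-time stochastic
process observed only at irregular panel times.  Three features make naive
per-joint Markov modelling inadequate:

* **clustering** — the 28 joints of a patient evolve under shared influences
  (disease flares, treatment changes), inducing strong within-patient,
  within-visit correlation;
* **history dependence** — a joint's past activity predicts its future
  activity and its damage risk, violating the Markov assumption for the
  marginal process;
* **a minimal-risk subpopulation** — a substantial fraction of patients never
  develop damage over decades of follow-up, suggesting a latent "stayer"
  class alongside the "movers" who carry damage risk.

`jointmsm` implements a clustered mover-stayer multistate framework that
addresses all three at the individual joint level, together with a synthetic
cohort generator so that the whole pipeline can be exercised and validated
without access to clinic data.

## The six-state model

Conditionally on the latent class, covariates and random effects, each joint
follows a time-homogeneous continuous-time Markov chain:

* **movers**: a four-state chain on {inactive/undamaged, active/undamaged,
  inactive/damaged, active/damaged}; activity is reversible, damage is
  absorbing in the sense that no transition leads back to an undamaged
  state;
* **stayers**: a two-state activity chain (inactive, active) that can never
  reach damage.

The intensities are parameterized with proportional-hazards regressions

* inactive &rarr; active: `l12 = lambda0_actgain * exp(beta_actgain' z + u)`
* active &rarr; inactive: `l21 = lambda0_actloss * exp(beta_actloss' z + alpha u)`
* undamaged &rarr; damaged (from the inactive state):
  `l13 = lambda0_dmg * exp(beta_dmg' z + v)`

and the remaining rates are proportional offsets that carry the clinically
interesting contrasts: `l24 = l13 * exp(beta_active)` (effect of current
activity on the damage rate), `l34 = l12 * exp(beta_damaged_actgain)` and
`l43 = l21 * exp(beta_damaged_actloss)` (effect of established damage on the
activity process), and `l56 = l12 * exp(beta_stayer_actgain)`,
`l65 = l21 * exp(beta_stayer_actloss)` (how stayers' activity dynamics differ
from movers').

`(u, v)` is a zero-mean bivariate normal pair with variances `sigma2_u`,
`sigma2_v` and correlation `rho`, drawn **independently for every
patient-interval** and shared by the patient's 28 joints over that interval
(the *observation-level* structure).  This represents non-predictable,
time-varying unobserved heterogeneity; the conventional *patient-level*
structure (one draw per patient, time-invariant heterogeneity) is available
as a comparator, fitted with the same number of parameters so likelihoods
are directly comparable.  The loading `alpha` lets the shared activity
frailty act with different sign/magnitude on the recovery rate.

### Dynamic covariates

The covariate vector `z` is rebuilt at every visit and treated as constant
over the following interval:

* **AMA (adjusted mean activity)** — the time average of the joint's
  activity path, approximated as the area under the linear interpolant of
  the observed binary activity values divided by elapsed time; a value in
  [0, 1] summarizing activity history.  It is undefined at the first visit,
  so the first observation interval is excluded from the likelihood (an
  option reinstates it with baseline activity as a proxy).
* **attained damaged-joint count** — the patient's current number of damaged
  joints (0-28), a measure of overall disease progression.
* **contralateral damage** — whether the same joint in the opposite hand is
  already damaged (damage is known to occur symmetrically).
* fixed covariates: joint-type dummies with the thumb proximal
  interphalangeal joint as reference (entering only the activity-gain and
  damage intensities; preliminary evidence shows no differential recovery
  rates), sex, age at arthritis onset (years), and arthritis duration
  (duration at clinic entry plus time in clinic, years, uncentred).

Conditioning on these history summaries is what buys back the Markov
assumption for the conditional process while the marginal process remains
non-Markov.

## The five-state reparameterization

When interest lies in *mean sojourn times* (how long a joint rests in a
state before any transition) and *jump probabilities* (where it goes when it
leaves), the damaged states are collapsed into one absorbing state, giving a
three-state mover chain, and the model is reparameterized through the smooth
bijection

```
l12 = (1 - p13) / mu1     l13 = p13 / mu1
l21 = (1 - p23) / mu2     l23 = p23 / mu2
l45 = 1 / mu4             l54 = 1 / mu5
```

with log-linear regressions on the mean sojourn times (`mu1`, `mu2`) and
logit-linear regressions on the jump-to-damage probabilities (`p13`, `p23`).
Covariate effects then act *directly* on interpretable quantities.  Random
effects enter the sojourn times through `u` (loading `alpha1` on the active
state) and the jump odds through `v` (loading `alpha2`), and the stayer
contrasts act on the sojourn times.  Both parameterizations describe the
same family of conditional chains; `sojourn_jump_to_intensities()` /
`intensities_to_sojourn_jump()` implement the bijection and are verified as
mutual inverses to 1e-12 in the tests.

## Likelihood

Under conditional independence of joints given `(u, v)` and the class, a
patient's interval contribution is the product over joints of transition
probabilities `P(dt) = exp(Q dt)`, integrated over the bivariate normal.
The integral is evaluated by factorizing the density as `phi(v | u) phi(u)`
and applying nested Gauss-Hermite quadrature (probabilist normalization) in
each dimension — 15 nodes per dimension by default for the
observation-level model, 30 for the patient-level model.  With
observation-level effects the random draws are independent across intervals,
so the patient likelihood is a product over intervals of per-interval double
integrals; with patient-level effects a single double integral wraps the
product over all intervals.

The mover-stayer mixture uses the observable indicator `c*`: patients with
damage at their last visit are necessarily movers and contribute
`(1 - pi) L(mover)`; damage-free patients contribute the full mixture
`(1 - pi) L(mover) + pi L(stayer)`.  A single stayer proportion `pi` is
shared by all patients.

Maximization is by BFGS on an unconstrained working scale (log for baseline
intensities and variances, atanh for `rho`, logit for `pi`), with standard
errors from the inverted central-difference Hessian and Wald intervals
formed on the working scale and back-transformed (hence asymmetric intervals
for variances and `pi`).  `profile_pi()` profiles the likelihood over `pi`
as an identifiability diagnostic: a locally concave profile with the argmax
at the full MLE indicates the stayer proportion is identified.

## Numerical choices

* **Transition probabilities.** The conditional chains are at most 4x4 and
  block upper triangular, so `exp(Qt)` has a closed form built from stable
  2x2 spectral formulas (all blocks of a generator have real eigenvalues);
  near-degenerate spectra fall back to scaling-and-squaring with a [6/6]
  Pade approximant, which is also the route used by the general-purpose
  `transition_matrix()`.  Both routes are validated in the test suite
  against an independent Runge-Kutta integration of the Kolmogorov forward
  equations (1e-7 entrywise) and against each other.  Entries negative by at
  most 1e-12 are clamped to zero and rows renormalized; anything worse
  raises an error rather than being masked.
* **Log-domain accumulation.** Products over 28 joints underflow in linear
  domain, so all per-interval products are accumulated as log sums with a
  log-sum-exp over quadrature nodes.
* **Caching.** Within one (interval, node pair, class), joints with
  identical covariate vectors share a single matrix exponential; grouping is
  precomputed once per fit.  This is exact, and effective because most
  joints of a patient share the all-zero dynamic-covariate history.
* **Rate clamping.** At extreme quadrature nodes the intensity regressions
  can overflow; rates are clamped at 1e10/year, far beyond anything
  data-relevant, keeping the exponentials finite without affecting realistic
  parameter values.
* **Optimization.** `optim(method = "BFGS")` with relative tolerance 1e-8
  and finite-difference steps of 1e-5; convergence is additionally checked
  with a central-difference gradient (warning above max-norm 1e-3).  The
  Hessian uses central differences with step 1e-4 (configurable).
  Starting values come from crude transition counts over person-time,
  ignoring clustering, with regression coefficients at zero, variances at
  0.5, `rho` at 0, and `pi` at one fifth of the observed damage-free
  fraction.
* **Quadrature accuracy.** The per-interval integrands are products of up
  to 28 conditional probabilities; when a large shared frailty draw produces
  many simultaneous transitions the integrand's mode shifts far from zero
  and plain Gauss-Hermite converges slowly.  The node sequence is Cauchy
  convergent and validated against Monte-Carlo integration in the tests;
  users studying datasets with heavy shared flares should check sensitivity
  to the node count rather than relying on any fixed default.

## The synthetic cohort generator

`simulate_cohort()` generates data from exactly the process the likelihood
assumes, so parameter recovery is a well-posed test of the estimator:

* patients draw a latent class (stayer with probability `pi`), sex
  (Bernoulli 0.55), age at onset (normal, mean 36.7, sd 13.3 years), and
  entry arthritis duration (gamma, mean 5.2, sd 7.2 years);
* visit counts are uniform on 4-12 and inter-visit gaps lognormal with mean
  10 months and sd 15 months, matching the visit-process moments of large
  psoriatic arthritis clinic cohorts;
* all 28 joints start undamaged, with entry activity Bernoulli(0.1) —
  near the typical observed mean AMA of about 0.09;
* per interval one `(u, v)` pair is drawn and shared by all joints; dynamic
  covariates are computed from the *observed* visit history (updated at
  visits only), exactly mirroring the fitted model's piecewise-constant
  assumption rather than an unknown continuous-time biology;
* each joint then evolves by exact event-driven simulation (exponential
  holding times, multinomial jumps), and only the states at visit times
  enter the observed dataset; the latent classes, frailties and event paths
  are retained in a sidecar record.

The default true parameter set uses clinic-scale magnitudes for the focal
parameters (`pi = 0.15`, `sigma2_u = 2`, `alpha = -0.38`, slow activation
with fast recovery, strong positive AMA effects).  Because the default
covariate set is reduced (AMA, contralateral damage, sex — no attained-count
feedback, no joint-type dummies), the damage baseline is set to
`log lambda0_dmg = -6.5` with `sigma2_v = 2`, absorbing the omitted strongly
positive damage covariates so that roughly a third of simulated patients
acquire damage over follow-up, in line with clinic cohorts.

What the generator deliberately does **not** emulate: informative visit
scheduling, dropout, treatment processes, measurement error in activity
assessment, and residual joint-level (as opposed to visit-level)
heterogeneity.  Passing recovery tests therefore demonstrates correctness of
the estimator under the model's own assumptions, not robustness to their
violation.

## Problem sizes used in the test suite

The automated tests run simulation-based checks at sizes chosen to keep the
full suite fast on a single core while remaining informative: the six-state
parameter-recovery study uses 200 patients x 28 joints with 4-12 visits and
7-node quadrature; the random-effect structure
comparison uses 10 replicates of 30 patients with a covariate-free model and
7-node quadrature; Monte-Carlo cross-checks use 1e5-1e6 draws.  Full-scale
analyses (hundreds of patients, 15/30-node quadrature) use exactly the same
code paths.

## Known limitations

* Intervals must contain complete 28-joint assessments; visits with missing
  joints are rejected at validation rather than partially used.
* `pi` is common to all patients; covariate-dependent stayer probabilities
  are not implemented.
* Random effects are independent over time (observation level) or constant
  (patient level); serially correlated frailties are out of scope.
* The conditional chains are time homogeneous between visits; time
  inhomogeneity is represented only through the dynamic covariates
  (including arthritis duration).
* Stayers share all covariate effects with movers in the activity
  intensities; the stayer contrasts act only through the proportional
  offsets, which is the most parsimonious reading of the intensity
  parameterization.

## A minimal session

```r
library(jointmsm)

cfg <- sim_config(n_patients = 50, seed = 1)
cohort <- simulate_cohort(cfg)
summarize_cohort(cohort)

config <- model_config("six_state", "observation", nodes = 7)
fit <- fit_mover_stayer(cohort$panel, config)
print(fit)

prof <- profile_pi(cohort$panel, config,
                   grid = seq(0.05, 0.3, by = 0.05), fit = fit)
plot(prof)
```
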