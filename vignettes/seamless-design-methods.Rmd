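---
title: "Methods: decision rules for seamless phase II/III designs with treatment selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision rules for seamless phase II/III designs with treatment selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and its model

`seamsel` studies a two-stage trial that merges a selection phase and a
confirmatory phase under one protocol. Stage 1 randomizes `m1` patients to
each of `K` experimental arms and a shared control; responses are normal with
known standard deviation `sigma`, and the estimands are the effects
`theta_i = mu_i - mu_0`. The arm with the largest estimated effect,
`i* = argmax theta_hat1_i`, is selected; if its estimate falls below the
futility threshold `ell` the trial stops with no rejection (an estimate
exactly at `ell` continues — a probability-zero event fixed for
determinism). Otherwise stage 2 randomizes a further `m2` patients to each of
arm `i*` and control, and a pre-specified rule tests `H0: theta_{i*} <= 0`
one-sided at familywise level `alpha`.

Because the stage-1 estimates share the control mean, their covariance is
`V = (sigma^2/m1)(I + J)` with unit diagonal inflation and correlation 1/2;
the simulator induces this structure exactly by drawing the `K + 1` arm means
and differencing. All decision statistics are functions of the standardized
summaries `(Z_{1,1..K}, i*, Z_{2,i*})` — never raw responses — which makes
fractional group sizes well defined and lets compared rules share one set of
underlying standard-normal draws. The control mean is fixed at zero in
simulation without loss of generality (every rule uses arm-mean differences
only); a test asserts decision invariance under a common location shift.

## The six standard decision rules

All critical values are calibrated so that the familywise error rate (FWER)
at the global null equals `alpha`, adjusting for the possibility of futility
stopping. Power differences between rules are then attributable to how they
combine the two stages, not to differing error rates.

* **Conventional**: stage-2 data only. A rejection requires continuation
  (null probability `K/(K+1)` when `ell = 0`), so the exact critical value is
  `qnorm(1 - alpha/p_cont)` — analytic, independent of `m2`.
* **TSE (pooled z)**: `w1 Z_{1,i*} + w2 Z_{2,i*}` with
  `w_i = sqrt(m_i/(m1+m2))`, equivalent to the information-weighted pooled
  effect estimate of the selected arm.
* **Closed testing with combination tests** (four variants): for every
  subset `I` of arms containing `i*`, a stage-1 intersection p-value
  (Simes, or Dunnett exploiting the equicorrelation 1/2) is combined with
  the stage-2 p-value `1 - Phi(Z_{2,i*})` by either the inverse chi-square
  rule `-ln(p1 p2)` or the inverse normal rule
  `w1 qnorm(1-p1) + w2 qnorm(1-p2)`; `H0_{i*}` is rejected when every
  intersection reaches the calibrated critical value. Only subsets
  containing `i*` matter for that rejection, and the stage-2 p-value uses
  `Z_{2,i*}` alone — the only arm with stage-2 data — following the standard
  adaptive combination-test construction.

The inverse chi-square statistic is exposed on the `-ln(p1 p2)` scale, so the
unadjusted reference value is the upper-`alpha` chi-square(4) quantile
divided by two (5.5716 at `alpha = 0.025`); calibrated critical values come
out slightly smaller because of futility stopping and the conservatism of the
intersection tests.

Two exact reductions make the closed test cheap at scale. For fixed `p2`
both combination functions decrease in `p1`, so the binding subset is the one
maximizing the stage-1 intersection p-value. Under Dunnett intersections
every subset containing `i*` has the same maximum statistic `Z_{1,i*}` and
the tail probability grows with subset size, so the full index set is always
binding. Under Simes the p-value is componentwise monotone, so for each
subset size the binding subset is `i*` plus the largest remaining p-values.
Tests verify both reductions against explicit enumeration of all `2^(K-1)`
subsets and against a brute-force closure oracle.

## Optimal rules as Bayes decision problems

To benchmark the rules above, the package derives the rule maximizing power —
the probability of selecting the truly best arm *and* rejecting its
hypothesis — for families of effect configurations, by recasting the
constrained frequentist problem as a Bayes decision problem: a discrete prior
(mass `1/(K+1)` on the null, the remainder spread over treatment-favouring
configurations), a reward for a correct rejection and a cost for a false one.
The Bayes rule rejects when the prior-weighted likelihood ratio of the data
under the favouring block versus the null exceeds a threshold; only the
cost *ratio* matters, so rules are parameterized directly by a threshold
calibrated to FWER `alpha` at the null.

With stage-1 log likelihood ratios linear in the estimates — coefficients
`lambda(phi) = V^{-1} phi = (m1/sigma^2)(phi - 1 sum(phi)/(K+1))` — three
families are implemented:

* **Single shape** `(gamma, ..., gamma, 1) * delta`: the statistic is linear
  and, divided through by `delta`, free of it: one calibration serves every
  effect size, so the rule is uniformly optimal across `delta` for its
  shape. At `gamma = 0.5` the non-selected coefficients
  `(2 gamma - 1)/(K+1)` vanish and the rule *is* the pooled-z rule — the
  package tests decision-by-decision identity. Below 0.5 the rule penalizes
  strong competitors; above, it borrows strength from them.
* **Permutation-averaged**, shapes strictly increasing: the statistic is a
  log-sum-exp over the `(K-1)!` configurations with the selected arm best.
  Exponents scale with `m1 delta / sigma^2`, so max-subtracted log-sum-exp
  is mandatory. The calibrated threshold moves with `delta`: no uniformly
  most powerful rule exists for these families.
* **Dose-ordered prior**: as above, but the mass of the block whose best arm
  is the top dose is concentrated on the sorted configuration. When a lower
  arm is selected the statistic coincides with the permutation-averaged one;
  when the top arm is selected the sum collapses to a single term carrying a
  `log((K-1)!)` mass offset.

The statistics are implemented as the exact log prior-weighted likelihood
ratios (including the quadratic normalizing terms), verified against a
full-density oracle that uses generic `solve()`/`determinant()` rather than
the closed-form `V^{-1} = (m1/sigma^2)(I - J/(K+1))`.

Strong FWER control from null calibration requires all statistic
coefficients to be non-negative; the minimum, in units of
`m1 delta / ((K+1) sigma^2)`, is `(K+1) gamma_1 - (1 + sum gamma_j)` —
positive for equally spaced shapes exactly when `gamma_1 > K/(K+2)`. Rules
failing the condition are flagged *pseudo-optimal*: they still bound the
attainable power (useful for efficiency benchmarks) but are not recommended
procedures. Error-rate spot checks away from the null are part of the test
suite for the recommended rules.

## Calibration

Every rule rejects, conditionally on stage-1 data and continuation, exactly
when `Z_{2,i*}` exceeds a threshold monotone in the critical value. The
default calibrator exploits this: it simulates only stage 1, computes each
replicate's exact conditional rejection probability (a normal tail), and
root-finds the critical value where the average equals `alpha`. This is
deterministic given the seed and has strictly smaller Monte Carlo error than
counting simulated stage-2 rejections — the remaining error is purely
stage-1 sampling noise. Two alternatives are provided and tested for
agreement: an empirical-quantile method on the per-replicate decision
statistics (the largest rejection fraction not exceeding `alpha`), and a
Robbins–Monro stochastic-approximation pass with the asymptotically
efficient gain (reciprocal of a pilot density estimate at the quantile) and
Polyak–Ruppert averaging. Exact quadrature for the pooled-z rule at the
five-arm reference design gives a critical value of 2.2390, which the
simulated calibrations reproduce to well within their standard errors.

## Power, efficiency, allocation and the value of stage-1 data

*Power* is the probability of selecting the best arm and rejecting its
hypothesis. Scenario families are evaluated with an independent uniform
permutation of the shape vector per replicate, success judged against each
replicate's own best arm. By default the stage-2 tail is integrated
analytically given stage-1 data, and compared rules share stage-1 draws, so
power differences are tightly coupled.

*Relative efficiency* of a rule against a benchmark is `100/rho`, where both
group sizes must be inflated to `(rho m1, rho m2)` — with recalibration at
every scale — for the rule to match the benchmark's power; `rho` is found by
a bracketed root search on the coupled, analytically smoothed power
difference, treating sample sizes as continuous (the known-variance model
makes this exact, and it removes step discontinuities from the search).

*Allocation*: with `(K+1) m1 + 2 m2` fixed, a direct search over integer
`m1` (real `m2`) recalibrates and re-evaluates the rule at every grid point
with common random numbers. The power maxima are flat, so the reported
optimum is the argmax of a `loess`-smoothed curve (span 0.35); the
selection/conditional-rejection decomposition is returned alongside.

*Value of stage-1 data*: the pooled-z rule at `(m1, m2)` attains power `P`;
a conventional analysis with the same selection stage needs `m2~` stage-2
observations per arm for the same power. Because the conventional power
factorizes into the simulated selection-and-continuation probability and an
exact normal tail, `m2~` is found by a monotone root search. The reported
statistic `r* = 100 (m2~ - m2)/m1` counts the extra stage-2 observations per
arm against the `m1` stage-1 observations per arm (equivalently total
`2(m2~ - m2)` against `2 m1` on the selected arm and control); values above
100 indicate that the non-selected arms' data also contribute. When a total
sample size is given, `(m1, m2)` are first optimized for the pooled-z rule,
matching the intended use of the statistic.

## What the simulations do and do not emulate

The generator reproduces the design's probability model exactly: normal
responses with known, homogeneous variance; a common control inducing
correlation 1/2; one selection point; selection purely on the primary
endpoint with ties broken to the lowest index. It does not emulate unknown
or heterogeneous variances, non-normal or delayed endpoints, safety-driven
selection, multiple interim looks, or unequal allocation — conclusions about
real trials carry over only to the extent that those simplifications hold.
Passing tests certify the implementation against this model and the
published operating characteristics of the reference design, not robustness
beyond it.

## Numerical choices and problem sizes

Dunnett intersection p-values use adaptive quadrature (relative tolerance
1e-10) with a Bonferroni tail fallback below 1e-13, where the quadrature
loses relative accuracy but the decision is already saturated; the
vectorized batch path interpolates `log p` on a 0.01-spaced grid over
`t` in `[-8, 7.5]` (error below 1e-8, verified against the scalar path and
an independent multivariate-normal oracle). Root searches use `uniroot`
with bracket expansion; the efficiency search brackets `rho` in `[0.3, 3]`
and errors on bracket failure rather than extrapolating. Zero p-values
saturate combination statistics at `+Inf` with a warning.

Default replication counts are `1e6` for final calibrations with a `2e5`
fast mode; the test suite and the acceptance script run at `3e4`–`3e5`
replicates (grid searches at `1.5e5` with common random numbers), sizes at
which the conditional calibrator's standard errors are an order of magnitude
below the tolerances being checked. Permutation families are enumerated
explicitly and rejected above `K = 8` (the reference analyses use `K = 5`,
where the per-selection sum has 24 terms).

## Worked example

```{r, eval = FALSE}
library(seamsel)
design <- seam_design(K = 5, m1 = 28, m2 = 140, ell = 0, sigma = 5,
                      alpha = 0.025)
reproduce_table1(design, replications = 2e5, seed = 1)

sc <- make_scenario(c(0.75, 0.8125, 0.875, 0.9375), delta = 2,
                    kind = "permutation")
bench <- seam_rule("optimal_permutation", design, scenario = sc)
relative_efficiency(seam_rule("tse", design), bench, sc,
                    replications = 2e5, seed = 1)
```
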