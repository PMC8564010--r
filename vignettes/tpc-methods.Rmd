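---
title: "Estimating and comparing thermal performance curves for binary survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing thermal performance curves for binary survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Many marine ectotherms develop through planktonic stages whose survival
depends strongly on water temperature, and the temperature experienced at
one early stage (fertilization, embryogenesis) can carry over to shape
performance at later stages. The experimental design this package serves
measures, for each combination of two prior-temperature factors, the
probability that an individual larva completes planktonic development at
each of a series of assay temperatures — a thermal performance curve (TPC)
for binary survival. The statistical questions are (i) whether the prior
environments change the shape or position of the TPC, and (ii) whether
interpretable curve descriptors — peak survival $P_{max}$, thermal optimum
$T_{opt}$, thermal breadth $T_{br}$, and critical limits $CT_{min}$,
$CT_{max}$ — differ among prior environments, with honest uncertainty.

## The model

Survival of individual $k$ in vial $v$ of block $b$, assayed at temperature
$T$, is Bernoulli with

$$\operatorname{logit} p = \eta_{fe}(T) + u_b + w_{v(b)},\qquad
u_b \sim N(0, \sigma^2_{block}),\quad w_{v(b)} \sim N(0, \sigma^2_{vial}),$$

where $\eta_{fe}(T)$ is a cubic polynomial in assay temperature whose
coefficients depend on the fertilization-temperature level $f$ and the
embryogenesis-temperature level $e$ (full factorial of the two factors with
the intercept, linear, quadratic, and cubic trend: $4 \times 2 \times 3 =
24$ fixed parameters for the default design). The cubic is parameterized in
an *orthogonal polynomial basis* built from the observation-level
temperature vector (replicates carry their multiplicity), so the per-degree
coefficients are the interpretable "linear / quadratic / cubic trends" and
are numerically well conditioned. The basis is built by the Forsythe
three-term recurrence and its recurrence constants are stored, so the same
polynomials can be evaluated exactly at any new temperature — essential for
descriptor extraction on a fine grid and for out-of-sample prediction.

Fitting maximizes the Laplace-approximated marginal likelihood
(`lme4::glmer`), the standard estimation scheme for binomial mixed models
with nested random intercepts. Before fitting, individual Bernoulli rows
are aggregated to one binomial count per vial; because all individuals in a
vial share covariates and random effects, the likelihood is unchanged and
fitting is much faster. Boundary fits ($\hat\sigma = 0$) are reported with
a flag rather than treated as failures, and complete separation (a
treatment cell with all-0 or all-1 outcomes) is flagged as non-convergence.

### Numerical choices

* Optimizer: nloptwrap's BOBYQA with explicit absolute stopping rules
  (`xtol_abs = ftol_abs = 1e-6`, `maxeval = 800`) and without the
  finite-difference derivative pass. With lme4's default stopping rules we
  observed refits on quasi-flat likelihood surfaces (small vials, variance
  estimates near the boundary) spending thousands of deviance evaluations
  polishing noise; the tight rules reach the same optimum (deviance
  agreement below $10^{-4}$ on test fixtures, predicted curves within 0.02
  on the logit scale) in a bounded number of evaluations. `fast = FALSE`
  restores the lme4 defaults.
* The fixed-effect covariance is the inverse Hessian block at the optimum
  with variance parameters held at their estimates — the standard Wald
  machinery for this model class. It conditions on $\hat\theta$; the
  consequences for test calibration are discussed below.
* Factor coding defaults to treatment contrasts (lowest temperature as
  reference); every reported quantity (curves, trends, Wald statistics,
  descriptors) is coding-invariant, and the test suite refits under sum
  coding to verify this.

## Inference on the fixed effects

`wald_tests()` reports the seven grouped terms of the full factorial
(fertilization, embryogenesis, their interaction, the thermal trend, and
the trend's two- and three-way interactions) with Wald $\chi^2$ statistics
under **Type-II marginality**: each term is tested after adjusting for
every term that does not contain it, ignoring those that do. The hypothesis
matrix for a term spans the component of its design columns orthogonal to
the non-containing columns, in the individual-level inner product (rows
weighted by vial size). This construction is invariant to factor coding and
reduces to the familiar marginal tests on balanced data; on the default
design the degrees of freedom are (1, 2, 2, 3, 3, 6, 6). A singular
hypothesis covariance is handled by eigen-pseudo-inverse with
rank-adjusted df and a warning.

`trend_contrasts()` reports, per embryogenesis temperature, the linear /
quadratic / cubic coefficients of the logit curve with fertilization levels
averaged with equal weights (the design is balanced by construction), and
all pairwise contrasts between embryogenesis temperatures. Contrast
p-values use the studentized-range (Tukey) adjustment for $k$ means with
infinite degrees of freedom — the asymptotic reference appropriate for a
model class with no residual-df concept.

### Calibration caveat

A simulation experiment in the acceptance suite shows that the
embryo-by-trend Wald test is **anticonservative in small block designs**:
with 5 blocks (15 individuals per vial) the null rejection rate at
$\alpha = 0.05$ is 0.094 at 500 simulations (0.12–0.15 in smaller pilots),
and about 0.08 even at the full 10-block design. A control experiment running the identical Type-II
construction on fixed-effects-only data (no random effects, large vials)
gives 3.5% at 200 simulations, so the construction itself is correctly
sized; the inflation comes from the asymptotic $\chi^2$ reference combined
with ML-estimated variance components at few blocks — a known property of
Wald tests in mixed models, not an implementation defect. The corresponding
acceptance criterion is therefore left red, with this analysis. Users with
few blocks should treat borderline Wald p-values with caution.

## Curve descriptors

Descriptors are functionals of the *population-level* curve: random effects
set to zero on the logit scale and fertilization levels averaged on the
logit scale (the descriptors characterize the embryogenesis groups, since
that is the factor of scientific interest). Because the inverse logit is
strictly increasing, all computations run on the cubic $\eta_e(T)$
directly:

* $T_{opt}$ — argmax over the search range (default: the assay range),
  from the stationary points of the cubic by the quadratic formula,
  compared against the endpoints; an endpoint winner is flagged
  `boundary`, and flat ties resolve to the smallest temperature.
* $P_{max} = \operatorname{logit}^{-1}\eta_e(T_{opt})$.
* Threshold crossings at a fraction $f$ of the peak — on the
  **probability** scale, $\eta_e(T) = \operatorname{logit}(f\,P_{max})$ —
  give $T_{br}$ (default $f = 0.5$; $f = 0.8$ available, and the suite
  verifies the 80% breadth is strictly narrower) and $CT_{min}, CT_{max}$
  (default $f = 0.05$). The nearest real root on each side of $T_{opt}$ is
  taken (closed-form roots, Newton-polished to ~1e-12 degC). Crossings may
  fall up to `extrapolation_margin` (default 10 degC) outside the assay
  range, flagged `extrapolated`; a side with no crossing before the cubic
  turns back, or beyond the margin, is flagged `censored`, set to the
  search limit, and excluded from bootstrap CIs.
* Thermal tolerance ($CT_{max} - CT_{min}$) is emitted as a derived
  convenience column only.

`grid_descriptors()` is a deliberately brute-force oracle (dense grid,
first-hit argmax, first-grid-point-past-threshold crossings) used to verify
the analytic extraction; the acceptance suite holds the two within
0.01 degC on 200 random cubics.

## Parametric bootstrap

`parametric_bootstrap()` propagates all model uncertainty to the
descriptors: each replicate draws fresh block and vial intercepts from the
fitted variances (the *unconditional* parametric bootstrap — the
conventional meaning of simulating "replicates of the regression model";
conditioning on the estimated modes would understate between-block
uncertainty), simulates binomial outcomes over the original design rows,
refits the mixed model, and re-extracts every group's descriptors.
Percentile 95% CIs (R's default linear-interpolation quantiles) are
reported per group and descriptor, plus replicate-wise pairwise differences
between groups with their own percentile CIs. Replicate $r$ uses a child
seed derived from the bootstrap seed, so results are independent of
execution order. Both of the field's significance rules are reported:
non-overlap of group CIs (conservative) and exclusion of zero by the
difference CI; the first implies the second on the same draws, which the
acceptance suite verifies on every bootstrap output.

### Replicate refits

By default each replicate is refitted with lme4's `nAGQ = 0` scheme
(`refits = "profiled"`): the variance parameters are optimized by Laplace
maximum likelihood with the fixed effects profiled out inside the penalized
IRLS loop. The full joint optimization (`refits = "joint"`) costs roughly
20x more per replicate, which puts a 1,000-replicate bootstrap of the
default design at hours rather than minutes on one CPU. Pilot coverage
experiments with identical seeds showed the two schemes statistically
indistinguishable on the descriptor scale: individual replicates can
differ by a fraction of the replicate spread (the schemes are different
estimators of the same quantity), but the draw distributions — centers,
spreads, and the resulting CI coverage — agree within Monte Carlo error,
which is what percentile CIs consume. The base fit, Wald tests, and
plug-in descriptors always use the full joint Laplace fit.

Bootstrap CIs at small designs (few blocks) tend to *undercover* slightly
(88.3% observed coverage for a nominal 95% over 300 CI checks at 5 blocks)
because ML variance estimates are biased downward — a property of the
procedure, not of the implementation; coverage at the stated acceptance
scale sits just inside the stated Monte Carlo band.

## The synthetic-data generator

Because the source study's individual-level data are not deposited, the
generator is the package's ground truth. It emulates the split-cohort
design: 2 fertilization x 3 embryogenesis temperatures, 10 assay
temperatures spanning 10–28 degC, 30 individuals per vial, 4 replicate
vials per combination (2 at 27 degC), and 10 blocks each assaying a subset
of 2–5 temperatures (the incomplete block structure). Blocks receive
temperature subsets by a seeded, quota-exact greedy allocation (largest
remaining quota into the block with most remaining capacity, random
tie-break): the study states only that temperatures were assigned
"haphazardly" under these quotas, so the allocation rule is our
construction; a deterministic `balanced` option (block $r$ gets every
temperature with quota $\ge r$) supports exact degenerate-case tests.

Default curve parameters place a shared logit-scale peak of 2 (peak
survival 0.88) with quadratic curvature 0.05 per degC$^2$ — matching the
closed-form test case and giving realistic TPC shapes (survival ~0.03 at
the cold end for an optimum near 20 degC) — and group-specific optima; the
default random-intercept SDs are 0.3 logit units at both levels, moderate
clustering for this kind of assay. A cubic skew term is available to probe
the fitted model's cubic trend. With both SDs zero the generator converges
on the inverse-logit curve by the law of large numbers, which the suite
tests at $n = 10^5$.

What a green test does **not** establish: the generator draws from exactly
the model the pipeline fits, so green results demonstrate correctness of
the inference chain, not robustness to model misspecification (real curves
need not be cubic on the logit scale; real vials may be overdispersed
beyond two random intercepts; monitoring mortality is not modelled).

## Known limitations

* No REML-type correction exists for the GLMM; variance components are ML
  and downward-biased at few blocks, with the calibration consequences
  noted above.
* Descriptors at "complete mortality" are not implemented (the logistic
  asymptote makes them ill-defined); the 5%-of-peak limits are the
  supported analogue.
* Proportion-aggregated input (numerator/denominator CSV) is not supported
  in v1; input is one row per individual.
* The Tukey adjustment assumes the three embryogenesis levels' trend
  estimates are jointly normal with the Wald covariance; with few blocks
  the same caveat as for the Wald tests applies.
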