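---
title: "Methods: selection inference for mtDNA population cages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection inference for mtDNA population cages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocage)
```

## The experimental design this package models

A perturbation-reperturbation population cage houses ~700 *Drosophila*
whose competing mtDNA haplotypes (2 or 3, on a fixed nuclear background)
start at equal numbers. Each discrete generation, adults lay for a fixed
window and are replaced by their offspring; a sample of flies (92 or 93)
is genotyped by PCR-RFLP at scheduled generations. After 9 generations,
48 mated females are isolated, genotyped through their offspring, and the
offspring pools are used to re-found the cage at equal haplotype numbers
for a second, 13-generation episode. The design asks whether haplotype
frequency change is directional (selection) and whether it is repeatable
across replicate cages and across episodes.

## Selection coefficients from log-frequency trajectories

For haplotype frequency $p(t)$ at generation $t$, a constant
per-generation selection coefficient $s$ implies
$\ln p(t) \approx \ln p(0) + s\,t$ while the haplotype is rare-to-common
but not near fixation. The per-cage estimator is the OLS slope of
$\ln \hat p$ on $t$ (`fit_cage_slope()`), with its conventional standard
error. We treat $\ln \hat p$ as the response and generation as the
predictor: that is the only orientation in which the slope has units of
per-generation change.

Two practical points:

* **Starting frequencies.** Founding numbers are equal by construction,
  but realized generation-0 frequencies scatter (survival to the end of
  the laying window, genotyping noise). The estimated generation-0
  frequency is used as the trajectory's origin — never the seeded ratio.
* **Zero estimates.** $\ln 0$ is undefined. The default drops
  zero-frequency generations and records them (`dropped_points`);
  imputation biases slopes. An optional continuity correction
  ($1/(2 n_{scored})$) is available for trajectories that touch zero
  transiently. At least 3 usable points are required per fit.

## Cross-cage summaries: the random-intercept model

Replicate cages share a haplotype's selection regime but differ in their
realized starting frequencies. The cross-cage model is

$$\ln \hat p_{cj} = \alpha + S\,t_{j} + u_c + e_{cj}, \qquad
u_c \sim N(0, v), \quad e_{cj} \sim N(0, r),$$

with a random intercept $u_c$ per cage. Both this model and the pooled
fixed-effects model are fit by **full maximum likelihood** so their
log-likelihoods are directly comparable. The fitter
(`fit_random_intercept()`) profiles the likelihood over the variance
ratio $\theta = v/r$: for fixed $\theta$ the GLS coefficients and the
residual variance are closed-form in group sums, leaving a
one-dimensional optimization. This makes a single fit cheap enough
(~0.5 ms) that resampling-based inference with thousands of refits is
practical, and the test suite cross-checks it against `lme4::lmer(REML =
FALSE)` and against a brute-force likelihood grid.

Under a **balanced design** — every cage observed at the same
generations — the mixed-model fixed slope $S$ equals the unweighted mean
of the per-cage OLS slopes, for any value of $\theta$. This identity is
what lets published per-cage coefficients be checked against their
published overall values without access to the raw data, and the test
suite verifies the pipeline reproduces all 16 published
haplotype-by-background-by-phase combinations this way.

### Repeatability

The repeatability of cage rank order is the intraclass correlation
$V_R = v/(v+r)$: the fraction of residual log-frequency variance
attributable to stable cage identity. Cages that keep their relative
positions across generations give $V_R$ near 1; trajectory crossing
gives $V_R$ near 0. Significance uses the likelihood-ratio statistic
$\Lambda = 2(\ell_{MEM} - \ell_{LM})$, floored at zero (ML can place the
variance on the boundary $v = 0$), against $\chi^2_1$. The 1-d.f.
reference follows the field's convention; for a variance component on
the boundary the asymptotic null is the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, so the reported p-values are
conservative (roughly doubled near the boundary). We keep the
conventional reference deliberately and note it here rather than
silently changing the published test.

### Confidence intervals

95% CIs for $S$ come from a seeded parametric bootstrap (default 5000
draws): simulate responses from the fitted model, refit, take percentile
2.5/97.5 of the refitted slopes. One refinement matters with only 4
cages: ML variance estimates divide by $n$ (and shrink $v$ toward the
boundary), so simulating from the ML components produces underdispersed
draws and slightly anticonservative intervals. The bootstrap therefore
simulates from **REML** variance components — the standard
small-sample bias correction — while $S$, $V_R$ and the LRT are reported
from the ML fit for likelihood comparability. Calibration is tested:
under the correctly specified model the interval covers the true $S$
93–97% of the time in 500 replicates.

The test suite also stress-tests the "selection" call (CI excluding
zero) under pure Wright-Fisher drift at census 700. That run is a
genuine misspecification test: a drifting trajectory is a random walk,
not independent noise around a line, and a random-intercept model
treats the walk's excursions as trend. At $N = 700$ over the pre-phase
schedule the walk contributes per-cage slope variance comparable to the
binomial genotyping noise, so the bootstrap CIs undercover and the
false-positive rate exceeds its nominal 5% (and the 10% bound the suite
asserts) — the classic inflation of regression on integrated noise.
This is a property of the log-frequency-regression methodology itself,
not of this implementation; drift-consistent calls at this census
should be read with that caveat, and the suite deliberately keeps the
failing assertion visible rather than widening the bound.

## The generative simulator

`simulate_cage()` / `simulate_experiment()` emulate the design so the
inference stack can be validated end to end:

* **Selection.** `relative_fitness` mode updates
  $p_i' \propto p_i e^{s_i}$ each generation — the standard haploid
  selection model, and only approximately log-linear. `log_linear` mode
  (2 haplotypes) moves the focal haplotype's expected log frequency by
  exactly $s$ per generation, so estimator-recovery targets are exact;
  it errors if the deterministic trajectory would leave $(0,1)$.
  Recovery studies use `log_linear`; realism studies use
  `relative_fitness`.
* **Drift.** The next generation's census is a multinomial draw from the
  post-selection frequencies (Wright-Fisher). The neutral variance after
  $t$ generations, $p_0(1-p_0)\bigl(1-(1-1/N)^t\bigr)$, is verified by
  simulation. Census sizes fluctuate log-normally around the target
  (default CV 0.15 in the analysis scripts; the study reports sizes
  fluctuated without giving a model) or stay fixed at `census_cv = 0`.
* **Genotyping.** Each sampled generation, 92/93 flies are attempted and
  each fails to score independently with probability calibrated to the
  published yields: $1 - 83.73/93 \approx 0.0997$ for the 2-haplotype
  assay and $1 - 85.63/92 \approx 0.0692$ for the 3-haplotype assay.
  Scored flies are multinomial in the true frequencies.
* **Reperturbation.** The 48 isofemales' haplotypes are drawn
  multinomially from the final pre-phase *estimated* frequencies (the
  genotyped sample — the information the experimenters actually had).
  Uniform sampling is assumed since no stratification is described; only
  the maternal haplotype matters for mtDNA, so mates are not modeled.
  Re-founding at equal numbers errors loudly if a required haplotype is
  absent among the isofemales.
* **Fecundity.** Offspring counts per isofemale are negative binomial
  (NB2: variance $\mu + d\mu^2$). The default $d = 0.33$ matches the
  residual mean square implied by the published melanogaster-on-OreR
  decomposition (~1178 at mean ~58). $d = 0$ is the deterministic
  limit (all counts equal the rounded mean), used for exact
  coefficient-recovery tests; note this differs from the Poisson limit
  approached as $d \to 0^+$.

What the simulator does **not** model: egg/larva/pupa stage structure,
density-dependent larval competition, mating dynamics, heteroplasmy, and
any nuclear variation segregating within a background. Passing tests
therefore show the estimator is correct under drift + binomial sampling
with (log-)multiplicative selection; they cannot rule out the
ecological mechanisms the study discusses as explanations for
non-repeatable episodes.

## Fecundity analysis

Offspring counts are analyzed by ordinary least squares on the raw
scale — matching the published linear-model tables, not a count GLM —
with treatment coding against the reference haplotype (mau12 in the
simulans sets, OreR in the melanogaster sets), two-sided t-tests, and a
one-way ANOVA decomposition with $R^2 = SS_{effect}/(SS_{effect} +
SS_{resid})$. For a 2-level factor $F = t^2$ exactly; the suite asserts
this to $10^{-9}$. The species contrast collapses haplotypes to
melanogaster vs simulans-clade via a fixed, overridable map. No
multiple-testing correction is applied (none was in the source tables).

## Numerical choices and problem sizes

* Profile optimization over $\log\theta \in [-30, 15]$ (Brent), with the
  $\theta = 0$ boundary evaluated explicitly; the better of the two is
  reported, so $v \ge 0$ always and degenerate fits land exactly on the
  boundary.
* $V_R$ is defined as 0 when $v + r = 0$ (noiseless identical cages).
* Ties in haplotype ranking are broken lexicographically and flagged.
* Bootstrap draw counts: 5000 in the analysis scripts (the published
  interval machinery used 5000 iterations); 400 inside the calibration
  test suites, where 500 replicates x 400 draws keeps the full
  calibration matrix near two minutes of CPU. Simulation-based checks
  use 500–2000 replicates (10,000 for the genotyping-yield
  calibration), sizes at which Monte-Carlo error is well below the
  tolerances asserted.

## Known limitations

* The log-linear estimator is biased for strong selection under the
  relative-fitness model (trajectory curvature near fixation); the
  recovery guarantees are stated for $|s| \le 0.11$ over the sampled
  schedules.
* With 4 cages, $v$ is estimated with 3 effective degrees of freedom;
  $V_R$ point estimates are noisy, which is why inference runs through
  the LRT rather than $V_R$ itself.
* Jensen bias in $\ln \hat p$ from binomial sampling
  ($\approx -(1-p)/(2np)$ per point) partially cancels across a
  trajectory but does not vanish; at $n \approx 92$ it is an order of
  magnitude below the recovery tolerance.
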