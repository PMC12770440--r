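---
title: "Multiobjective stratification of clinical response: methods and design"
author: "MOAstrat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective stratification of clinical response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MOAstrat)
```

# The problem

Intervention trials in Parkinson's disease (and many other conditions)
measure response on several conflicting endpoints at once: a motor
examination (MDS-UPDRS III, lower is better), a cognitive screen (PANDA,
higher is better) and an olfactory test (higher is better). A patient may
improve on one scale while worsening on another, so any single-endpoint
responder definition discards part of the signal. MOAstrat implements a
multiobjective view of response: patients are compared by Pareto dominance
on their endpoint changes, sorted into fronts, and the extreme fronts
define best- and worst-responding clusters. Physiological parameters
(e.g. immune-cell subset frequencies, in % of PBMC) measured alongside the
endpoints are then ranked by how strongly they co-vary with cluster
membership — without any distributional assumptions on the parameters,
which typically live on wildly different scales.

# The procedure

## Oriented endpoint changes

For every patient and endpoint we compute the change from baseline to the
follow-up visit V2 and orient it so that *smaller is always better*:
higher-is-better endpoints are sign-flipped at ingestion
(`objectiveDeltas()`). A clinical improvement is therefore always a
negative entry, and the Pareto machinery never needs to know endpoint
directions. This canonicalization is testable: flipping a direction flag
negates exactly that column.

Patients missing either visit for *any* endpoint are excluded
(complete-case analysis) and reported with reasons — never silently
dropped. With a single dropout in a typical cohort this matches an
analysis of completers; the package does not impute clinical scores.

## Nondominated sorting

Patient $X$ dominates patient $Y$ when $f_i(X) \preccurlyeq f_i(Y)$ for
every objective $i$ and $f_j(X) \prec f_j(Y)$ for at least one $j$, where
$\prec$/$\preccurlyeq$ mean better / equal-or-better (in canonical
orientation, $\le$ and $<$). This is standard weak Pareto dominance with a
mandatory strict improvement; equal rows are mutually nondominated and
always share a front. Front 1 is the set of patients dominated by nobody;
removing it and repeating yields fronts $F_1 \dots F_w$
(`nondominatedSort()`). The implementation is the $O(MN^2)$ count-based
fast sort, but its output is defined — and tested — to equal the iterative
peeling definition exactly; an independent quadratic-scan oracle
(`paretoFrontOracle()`) is part of the public API so any analysis can be
re-verified.

Comparisons are exact floating-point comparisons with no tolerance:
endpoint deltas are small integers or half-points, and a tolerance would
merge genuinely different scores.

## Extreme clusters

`selectExtremeClusters()` takes the fraction $q$ (default 0.20) of
patients with the lowest front numbers as the best-response cluster A1 and
the $q$ with the highest as the worst-response cluster A2. The target size
is $\mathrm{round}(qN)$, rounding half up (72 patients at $q=0.2$ give
clusters of 14). When a front straddles the cutoff, its members are
ordered by the sum of their per-objective ranks (ascending for A1,
descending for A2; residual exact ties by patient id) and truncated to the
target size. Rounding and tie-break are deterministic, data-driven, and
recorded both in the `ClusterLabels` object and in the run manifest.

## Rank-normalized parameter association

For every physiological parameter we compute the log fold change
$\ln(\mathrm{V2}/\mathrm{baseline})$ (`featureLogRatios()`). Because
immune-subset frequencies can be exactly zero, nonpositive values are
handled by an explicit pseudocount policy: by default each nonpositive
value is replaced by half the smallest positive value observed for that
parameter across the cohort (`half_min`); alternatively the affected cell
can be excluded (`exclude`). Every application is logged per cell.

The log-ratios are then converted to cohort-wide ranks (average ranks for
ties) and z-scored per parameter to mean 0 and sample standard deviation 1
(`rankNormalize()`). Ranking over *all* patients — not within clusters —
is deliberate: within a cluster, the mean of the normalized ranks then
measures how far that cluster deviates from the rest of the population,
and the standard deviation how concentrated the cluster is on that
parameter's scale (`clusterFeatureStats()`). Both statistics are invariant
under any strictly increasing transform of the raw parameter, which is
what makes parameters on arbitrary scales comparable.

## Second-stage parameter ranking

Within each cluster, parameters with high deviation ($|\text{mean}|$) and
low variation (sd) are the interesting ones — itself a two-objective
problem with a conflict. `rankParameters()` therefore reuses the
nondominated sort in the space $(-|\text{mean}|, \text{sd})$: front 1
contains the parameters most strongly associated with that cluster's
response. The magnitude $|\text{mean}|$ is used (rather than the signed
mean) because a parameter may deviate in either direction; signed means
are always reported alongside. Separate rankings are produced for A1 and
A2; for recovery evaluation the two front-1 sets are pooled (a parameter
is "found" if either extreme cluster flags it), mirroring how best- and
worst-response parameter sets are usually displayed together. Degenerate
(constant) parameters and cluster/parameter pairs with fewer than two
observations are flagged and excluded from the ranking, never silently
scored.

No p-values are attached: the method exists precisely because the
parameters' scales and distributions vary too much for a common parametric
test, and the ranking is descriptive.

## Single-endpoint responder rules

Two conventional definitions are provided for comparison
(`classifyResponders()`): *strict decrease* (responder iff MDS-UPDRS III
V2 < baseline) and *median split* on the percent change
$100(\mathrm{V2}-\mathrm{baseline})/\mathrm{baseline}$, pooled across
arms, with patients exactly at the median labeled nonresponders —
consistent with the "$\ge$ baseline $\Rightarrow$ NR" convention of the
strict rule. Patients with baseline 0 cannot have a percent change and are
excluded with a warning.

## Study design: ANOVA power

`anovaPower()` implements fixed-effects one-way ANOVA power via the
noncentral F distribution with noncentrality $\lambda = f^2 N$ (Cohen's
$f$; the G*Power convention): power is the probability that a noncentral
$F(k-1,\,N-k,\,\lambda)$ variate exceeds the central-F critical value.
With $f = 0.4$, $\alpha = 0.05$ and $k = 3$ groups, a total of $N = 72$
(24 per group) gives power 0.8534928; `requiredSampleSize()` finds the
smallest (optionally balanced) $N$ reaching a target power by scanning the
monotone power curve. The closed form is cross-checked against a simulated
one-way ANOVA in the test suite.

```{r power}
anovaPower(f = 0.4, alpha = 0.05, k = 3, nTotal = 72)
requiredSampleSize(f = 0.4, alpha = 0.05, k = 3, targetPower = 0.85)
```

# The synthetic cohort generator

No per-patient table from a real supplementation trial is bundled;
instead `simulateCohort()` generates cohorts with exactly the statistical
structure the analysis assumes, so every stage can be validated against a
known ground truth:

* a latent responsiveness variable $r_p \sim N(0, \sigma_r^2)$ per
  patient drives *correlated* improvement across all endpoints;
* each endpoint's V2 score is baseline plus an oriented effect
  (points per latent sd) plus Gaussian noise, integer-rounded and clamped
  to the score's range;
* *planted* parameters have log-ratios constructed as
  $\rho\, r_p/\sigma_r + \sqrt{1-\rho^2}\,\varepsilon$ — jointly Gaussian
  with the latent variable, so the target correlation $\rho$ is exact in
  population; *noise* parameters are independent standard normals;
  baselines are lognormal (strictly positive, like %-of-PBMC
  frequencies);
* missingness, if requested, is injected completely at random;
* every draw derives from one seed, and the caller's RNG state is
  restored afterwards.

Default shape: 72 patients in 3 equal arms; baseline score distributions
(MDS-UPDRS III $\approx N(33, 10^2)$ clamped to its range, PANDA
$\approx N(18, 5^2)$ on 0–30, olfactory $\approx N(8, 3^2)$ on 0–16) and
effect/noise scales (4/4 points for the motor score, 1.5/1.5 for the
other two, i.e. each endpoint's oriented delta correlates ≈ 0.7 with the
latent variable) are *synthetic defaults chosen for clinical
plausibility* — moderate-stage cohorts, clinically meaningful motor
changes of a few points — not estimates from any particular study.

What the generator does **not** emulate: arm-specific effects (all arms
share one latent-response model, since the stratification pools arms),
informative missingness, floor/ceiling pile-ups beyond simple clamping,
longitudinal visits beyond baseline/V2, and correlated noise *between*
parameters. Passing recovery benchmarks on these cohorts therefore shows
the pipeline recovers planted monotone associations under clean
assumptions; it does not certify behavior under structured real-world
artifacts.

# Validation benchmarks and their sizes

The test suite validates the sorting engine against a brute-force peeling
oracle on 1000 random instances (≤ 50 patients, 2–4 objectives, with and
without ties), checks transform invariance on 100 instances, and checks
the rank-z normalization identity to 1e−9. The recovery benchmark uses
100 cohorts of 80 patients with 3 planted parameters at $\rho = 0.8$
among 27 noise parameters ($q = 0.2$), plus 50 cohorts per point on the
$\rho$ grid $\{0, 0.2, 0.4, 0.6, 0.8\}$; a null benchmark at $\rho = 0$
checks that no parameter is systematically enriched on front 1. These
sizes keep the whole suite within a few minutes on one core while leaving
Monte-Carlo error well below the effects being checked.

# Known limitations

* **Front-1 recovery of several equally planted parameters has a
  combinatorial ceiling.** When $k$ planted parameters carry exchangeable
  signal, their within-cluster $(|\text{mean}|, \text{sd})$ pairs are
  i.i.d. draws from one distribution, and one planted parameter can
  Pareto-dominate another. With independent coordinate fluctuations the
  expected fraction of $k$ exchangeable points on a 2-D Pareto front is
  $H_k/k$ (≈ 0.61 for $k = 3$) — and near the top of the rank scale the
  mean and sd fluctuations become negatively correlated, pushing
  per-cluster recovery lower still (≈ 0.43 in the default benchmark).
  Pooling the A1 and A2 front-1 sets raises measured mean recovery to
  ≈ 0.67–0.69, where it plateaus in $\rho$. This is a property of strict
  front-1 membership, not an implementation defect: the dominated planted
  parameters sit on front 2 with near-identical coordinates. Analyses
  that need a *set* of candidate parameters should read the first few
  fronts (or front 1 of both clusters), not front 1 of one cluster alone.
* Dominance is exact; endpoints measured with continuous noise will
  rarely tie, making fronts finer than with integer scores.
* Complete-case exclusion can bias clusters if missingness is
  response-related; the generator only models MCAR missingness.
* The pseudocount policy affects log-ratios of parameters with zeros;
  both the policy and each application are recorded in the manifest so
  the sensitivity is auditable.

# Reproducibility

`runMoa()` consumes a single config (list or YAML), uses one seed for any
synthetic input, and records every output-affecting policy — dominance
form, rounding, tie-break, pseudocount, $q$, counts per stage — in a
manifest. Output bundles contain no timestamps: identical configs give
byte-identical bundles, which the test suite asserts.
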