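---
title: "Methods: dominance hierarchy inference and sex-specific stress outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance hierarchy inference and sex-specific stress outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domstress)
```

This vignette documents the statistical model behind each stage of the
package, the parameters that matter and their defaults, the design
choices that were genuinely open, and what the synthetic-data
generators do and do not emulate.

## Dominance inference

The input is a long-format chase-event log: one row per (group, day,
phase, actor, recipient) with a count. Win matrices aggregate these
into directed counts `s_ij`; the roster — the union of actors and
recipients, or an explicit roster file — fixes the group size N, which
matters because an animal that never chases and is never chased still
dilutes the normalization.

For each dyad with `n_ij = s_ij + s_ji > 0` interactions, the raw win
proportion is `P_ij = s_ij / n_ij`. The David's Score accumulates
direct and opponent-weighted wins minus the mirror-image losses:

\[
DS_i = w_i + w_{2,i} - l_i - l_{2,i}, \qquad
w_i = \sum_j P_{ij}, \quad w_{2,i} = \sum_j P_{ij} w_j,
\]

with `l` terms defined on the transposed matrix. The normalized score
`(DS_i + N(N-1)/2)/N` lies in `[0, N-1]`.

Three conventions were open and are now fixed defaults, each with an
escape hatch:

* **Zero-interaction dyads** contribute `P_ij = P_ji = 0`, the
  conventional treatment for sparse observation windows; an option
  (`zero_dyad = "half"`) instead treats an unobserved dyad as
  uninformative (0.5). The zero convention keeps a never-interacting
  animal at the bottom of the scale rather than the middle.
* **Raw vs chance-corrected proportions.** The corrected dyadic index
  `D_ij = P_ij - (P_ij - 0.5)/(n_ij + 1)` shrinks sparse dyads toward
  0.5. The package defaults to raw proportions because only the raw
  form attains the exact 0..N−1 endpoints of the normalized scale that
  the downstream boundary checks rely on; `corrected = TRUE` is a
  flag everywhere.
* **Cumulative scores** pool chase counts across the baseline window
  before scoring (`mode = "pooled"`). Summing per-day scores instead
  (`mode = "sum_daily"`) weights an almost-silent day as much as a
  busy one and is provided only for sensitivity analysis. Pooling
  stabilizes dyads that interact rarely on any single day.

Ranks 1..N (α through δ for N = 4) follow descending normalized score.
Ties — common in single-day windows of sparse groups — are broken by
total chases initiated, then roster order, deterministically; the
number of tie-break events is recorded on the rank vector so analyses
can flag windows where ranking hinged on the tie rule.

## Hierarchy structure metrics

* **Steepness**: absolute OLS slope of the sorted normalized scores on
  rank positions 1..N. On the normalized scale the slope is bounded by
  1 (power falls linearly from N−1 to 0), which is why steepness is
  always computed from normalized rather than raw scores. A constant
  score vector yields 0, not an error.
* **Despotism**: the α's share of all chases initiated; 1/N is the
  uniform reference.
* **Directional consistency**: the pooled form
  `Σ(H_d − L_d) / Σ(H_d + L_d)` over interacting dyads, where H and L
  are each dyad's larger and smaller directed counts. "Average
  fraction" is ambiguous between pooling and averaging per-dyad
  fractions; both are implemented (`method = "pooled"` default,
  `"mean"` optional) and both equal 1 in the fully one-directional
  case. Note this index measures direction-by-frequency; it is
  agnostic about whether the majority direction runs down the
  score gradient.
* **Landau's modified h′**: the binary relation sets i over j when
  `s_ij > s_ji`; tied (`s_ij = s_ji > 0`) and unknown (`n_ij = 0`)
  dyads are oriented uniformly at random in each replicate, and
  `h = 12/(N³−N) Σ(V_i − (N−1)/2)²` is averaged over replicates. The
  right-tail p-value is the proportion of fully random tournaments
  whose h reaches the observed h′. The default of 10,000 replicates
  holds the across-seed standard deviation of h′ below 0.02 for N = 4;
  the seed is an explicit parameter and is applied locally so callers'
  RNG streams are untouched. With no undecided dyads the randomization
  is inert and h′ is exact.

## Rank stability and persistence

Daily ranks are computed per baseline day; the final rank comes from
the cumulative profile. For each pair of consecutive days an animal
scores a success when its daily rank is unchanged — D−1 trials over D
days — and trials are aggregated by sex and final rank. Comparing to
the previous day's *daily* rank (rather than the cumulative rank) is
the reading consistent with per-stratum trial counts of 3 per animal.
The chance level defaults to 1/N (25% for groups of four), verified in
the tests by enumerating all 4! permutations, and the test is the
exact upper-tail binomial probability `P(X ≥ k | n, p0)`. Odds ratios
against chance are reported with `k = 0` and `k = n` mapped explicitly
to 0 and infinity.

Persistence across an acute stressor is the Pearson correlation
between matched baseline and post-stressor scores (two-sided p, t
distribution, n−2 df). The chase-rate change analysis log(x+1)
transforms per-animal totals — the +1 admits animals with zero
post-stress chases — and fits a two-way mixed ANOVA (between: sex;
within: stage; error stratum: subject), reported with (1, n−2) df.
For a two-level within factor this is algebraically a difference-score
analysis, which is exactly how the test suite's independent oracle
recomputes the sums of squares. When both stages are numerically
identical for every subject the F ratio is 0/0; the package reports
F = 0, p = 1 (no evidence of change) rather than NaN.

## Outcome preprocessing and modelling

The preprocessing order is: (1) stratum outlier masking, (2) exclusion
by missingness, (3) median imputation, (4) Blom transform, (5) batch
adjustment, (6) reference centering. The order was open; this sequence
ensures the rank-normalization and the batch model see complete data,
and that exclusion decisions depend only on raw missingness, never on
downstream transforms. Each step logs what it did (outlier log,
exclusion list, imputation log) on the returned object.

* **Outliers**: values more than 3.5 SD from their sex-by-condition
  stratum mean are set to missing. With fewer than about 13
  observations in a stratum the sample z-statistic cannot reach 3.5
  (its maximum is `(n−1)/√n`), so the rule is effectively inert in
  tiny strata — a property worth knowing when applying it to pilot
  data.
* **Missingness**: animals missing more than 2 readouts (after
  masking) are excluded; the remainder are median-imputed per
  variable.
* **Blom transform**: `qnorm((r − 3/8)/(n + 1/4))` with average ranks
  for ties; missing values pass through; constant vectors map to zero
  with a warning.
* **Batch adjustment**: per variable, standardized residuals of a
  linear model on batch as a factor; with a single batch this is
  z-scoring. Batch means of the output are zero by construction.
* **Reference centering**: finally values are re-expressed relative to
  the female-control mean, so effect displays read as deviations from
  unstressed females. This is presentation-level: it shifts columns by
  constants and does not affect any F, t, or correlation statistic.

PCA uses SVD on centered, unit-variance columns (constant columns are
dropped with a warning); scores are left singular vectors scaled by
singular values and per-component variance explained is
`σ_k²/Σσ²`. Group effects on a component are a two-way ANOVA
(sex, condition, interaction, sequential sums of squares with the
interaction last). The dominance effect is fitted *within* a condition
as `score ~ DS + sex + DS:sex`; the interaction F with (1, n−4) df
tests whether the dominance slope differs by sex, and per-sex OLS
slopes are attached for sign inspection. Correlation screens use
Spearman's rho with BH adjustment within each sex's family (or
Bonferroni across the family), skipping readouts with fewer than four
complete pairs. Single-variable condition screens pair the two-way
ANOVA with two-sided Welch t-tests within each sex —
Welch because unequal variances between control and stressed groups
are the norm, and fractional Welch–Satterthwaite df make that choice
auditable — plus an optional Kruskal–Wallis test for ordinal scores.
Normality and variance-homogeneity diagnostics are deliberately not
used to switch tests silently; the test actually run is always named
in the output.

## Synthetic generators

`simulate_chases()` is a minimal Bradley–Terry-style model: latent
abilities `θ_i ~ N(0, τ²)` per animal; per day and unordered dyad an
encounter count `K ~ Poisson(λ)`, each encounter won by i with
probability `logistic(β(θ_i − θ_j))`; one post-acute day at rate ρλ.
Defaults — groups of four, four baseline days, τ = 1, β = 3, λ = 8
encounters per dyad per day, ρ = 0.5 — produce per-group daily chase
totals in the tens and clearly structured but imperfect hierarchies,
the regime the analysis is designed for. Sex is a pure label; sex
differences in hierarchy structure are emulated by running the two
sexes at different β/λ presets rather than by a structural mechanism.

`simulate_outcomes()` adds, per variable: a small random intercept,
a batch offset, sex and condition main effects, Gaussian noise, and —
on a configurable fraction of "shared-factor" variables — a
dominance-by-sex interaction confined to the stressed condition with
slope +γ in males and −γ in females on centered dominance.
Missingness is completely at random.

What the generators do **not** emulate: overdispersed or temporally
autocorrelated encounter rates, rank dynamics (abilities are constant
within a phase), coalition or winner/loser effects, structured
(informative) missingness, heavy-tailed readouts, and any real
relationship between an animal's chase behavior and its outcome values
beyond the planted interaction. Passing the recovery and calibration
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to these real-data features.

## Problem sizes and numerical choices

The test suite runs the oracle comparison on 1,000 random win matrices
(N 3–6, counts ≤ 20) at 1e-9, the mixed-ANOVA oracle on 200 random
unbalanced datasets, null calibrations at 500 replicates per test
(rejection bands 0.05 ± 0.02), the ability-recovery check on 500
simulated groups, the end-to-end planted-interaction recovery on 100
datasets of 96 animals, and the metric-monotonicity trend on 200
groups per discriminability level with 100 h′ replicates — sizes
chosen so each property estimate's Monte-Carlo error is well inside
the asserted margin. Equality tolerances are 1e-9 for algebraic
identities and 1e-8 for SVD reconstruction; randomized procedures take
explicit integer seeds and are bit-reproducible given them.

## Interfaces

The package is function-first: every stage takes a data frame and
returns a tibble, so pipelines compose with the pipe, and `run_all()`
orchestrates the full chain from one YAML or list config, writing
per-stage CSVs and a versioned JSON report that echoes the config and
all seeds. A shell-level binary is deliberately not shipped: the
intended users work in R, and `Rscript -e` plus `run_all()` covers
batch execution.

## Known limitations

* The David's Score normalization assumes every roster animal could in
  principle interact with every other; isolated-by-design housing
  layouts would need a different normalization.
* h′ p-values compare against fully random tournaments, not against
  degree-preserving randomizations; with very sparse matrices the test
  is conservative.
* The interaction model is fixed-effects only; group-level random
  intercepts are out of scope, so groups contribute pseudo-replicated
  animals to the condition-level tests exactly as in the classical
  analysis this package mirrors.
* With λτβ small, daily ranks are tie-dominated and the deterministic
  tie-break (chases initiated, then roster order) materially shapes
  maintenance counts; the tie-break log should be inspected before
  interpreting stability in sparse data.
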