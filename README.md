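# domstress

Social dominance hierarchies from chase events, and what they predict
about stress outcomes.

Group-housed mice form dominance hierarchies that can be read out of
automated home-cage observation: who chases whom, and how often. This
package implements the full analysis chain for such data:

1. **Hierarchy inference** — David's Scores from dyadic chase counts,
   normalized to the 0..N−1 scale, with ordinal ranks (α, β, γ, δ for
   groups of four).
2. **Hierarchy structure** — steepness, despotism, directional
   consistency, and Landau's modified h′ linearity with a
   randomization p-value.
3. **Stability** — daily rank trajectories, rank-maintenance counts
   tested against the 1/N chance level with exact one-tailed binomial
   tests, Pearson persistence of scores across an acute stressor, and
   a repeated-measures ANOVA on log chase counts.
4. **Outcome modelling** — rank-based inverse-normal (Blom)
   transformation, batch adjustment by standardized residuals,
   stratum-wise outlier masking, median imputation, PCA by SVD, and
   the dominance-by-sex interaction model applied within a stress
   condition, plus Spearman correlation screens with BH or Bonferroni
   control.
5. **Synthetic data** — a Bradley–Terry-style latent-ability chase
   simulator and a structured outcome simulator, so the whole pipeline
   is testable without animal recordings.

It is aimed at behavioral neuroscientists and computational
ethologists who have per-dyad agonistic interaction counts (from a
Social-Box-like system or manual scoring) and post-intervention
phenotyping tables.

## The core statistic

For animals *i*, *j* with directed chase counts *s_ij*, the dyadic win
proportion is *P_ij = s_ij / (s_ij + s_ji)* (0 for dyads that never
interacted). The David's Score is

```
DS_i = w_i + w2_i − l_i − l2_i
w_i  = Σ_j P_ij          w2_i = Σ_j P_ij · w_j
l_i  = Σ_j P_ji          l2_i = Σ_j P_ji · l_j
```

and the normalized score `nDS_i = (DS_i + N(N−1)/2) / N` ranges from 0
(most subordinate) to N−1 (most dominant); 0–3 for groups of four.
Hierarchy steepness is the absolute OLS slope of the sorted normalized
scores on rank positions 1..N; despotism is the α's share of all
chases; directional consistency is Σ(H−L)/Σ(H+L) over dyads; Landau's
modified h′ randomizes tied/unknown dyads and averages
`h = 12/(N³−N) · Σ(V_i − (N−1)/2)²`.

## Worked example

```r
library(domstress)

log  <- simulate_chases(chase_sim_config(n_groups_per_sex = 6, seed = 42))
dominance_profile(log, "M_G01", days = 1:4)
#> # dominance_profile: group M_G01 | phase baseline | days 1,2,3,4
#> # A tibble: 4 × 7
#>   individual_id group_id sex       ds norm_ds  rank chases_initiated
#> 1 M_G01_m1      M_G01    male  -2.65    0.837     4               30
#> 2 M_G01_m2      M_G01    male  -2.38    0.906     3               28
#> 3 M_G01_m3      M_G01    male   4.40    2.60      1               73
#> 4 M_G01_m4      M_G01    male   0.626   1.66      2               60
```

Animal `m3` is the α: it wins most of its dyads, its normalized score
2.60 approaches the maximum of 3, and it initiated 73 of the group's
191 chases. Hierarchy structure for the same group:

```r
hierarchy_metrics(log, "M_G01", days = 1:4, n_rand = 10000, seed = 7)
#>   group_id steepness despotism   dci h_prime h_prime_p
#> 1 M_G01        0.604     0.382 0.539       1     0.374
```

A steepness of 0.60 is a moderately despotic, fully linear (h′ = 1)
hierarchy; the h′ randomization p of 0.37 reflects how often a random
4-tournament is also linear. Rank stability over the four baseline
days, stratified by sex and final rank:

```r
traj <- daily_trajectories(log, baseline_days = 1:4)
maintenance_counts(traj)
#>   sex    final_rank     k     n    p0  p_value odds_ratio_vs_chance
#> 1 female          1    16    18  0.25 2.08e- 8                24
#> 5 male            1    18    18  0.25 1.46e-11               Inf
#> ...
```

Each animal contributes one trial per consecutive-day pair (3 trials
over 4 days); α-males here kept their rank in 18/18 trials, far above
the 25% chance level (exact upper-tail binomial p = 1.5×10⁻¹¹).

The outcome side takes a table of post-stress readouts with
`sex`/`condition`/`batch` metadata, normalizes and batch-adjusts it
(`preprocess_outcomes()`), decomposes it (`outcome_pca()`), and tests
whether baseline dominance predicts the leading component in a
sex-specific way within the stressed condition
(`ds_sex_interaction()`). `run_all()` drives every stage from one YAML
or list config and writes per-stage CSVs plus a JSON report.

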