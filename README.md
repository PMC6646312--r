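# oralsuccession

Statistical machinery for characterizing how the oral microbiome is
acquired over the first year of life, from longitudinal 16S rRNA gene
count tables of mother–child dyads.

Saliva samples from infants are sparse, low-biomass and unevenly sized
(library totals spanning roughly 10² to 10⁴ sequences), and subjects are
sampled repeatedly. The package implements the resampling-based analyses
this kind of cohort needs:

- **Double-rarefaction core membership.** Which species are *consistently*
  part of the infant, toddler, or mother community? Each iteration rarefies
  every sample to the smallest library size, sums rarefied counts within
  each (subject, group) unit, rarefies each unit again to the smallest
  combined total, and records which species are observed in each group.
  Over 1000 iterations this yields an empirical inclusion probability per
  species and group; species at ≥ 0.95 are called members. The two stages
  correct simultaneously for unequal library sizes and unequal per-subject
  sampling frequency.
- **Venn membership and shared-core contribution.** Included species are
  assigned to the 7 regions of the infant/toddler/mother Venn diagram, and
  the summed relative abundance of the fully shared set is computed per
  sample (the "how much of the community is core?" statistic).
- **Succession ordering.** Monthly samples are pooled into 3-month
  intervals per child, each pool rarefied once to a common depth, and each
  species' prevalence across subjects computed per interval. A species'
  *acquisition interval* is the first interval in which it is detected in
  ≥ 75% of children; species present in < 50% of subjects overall are
  dropped.
- **Community comparisons.** Bray–Curtis dissimilarities
  (`d = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`), NMDS ordination (Kruskal stress-1, via
  vegan), one-factor PERMANOVA (Anderson pseudo-F with label permutation,
  including exact enumeration on small designs), rarefied Shannon/richness
  with Kruskal–Wallis and BH-adjusted Mann–Whitney post-hocs.
- **Convergence over time.** Per-sample distance to the all-children
  centroid along the first NMDS dimension, regressed on age with a linear
  mixed model (random intercept per subject): a negative slope means
  children's communities converge toward a shared profile.
- **Life-event comparisons.** Paired pre/post samples around solid-food
  introduction and first tooth eruption ("immediately pre/post" = nearest
  samples), Wilcoxon signed-rank tests on rarefied richness, diversity,
  and per-species relative abundances (BH-adjusted).
- **A synthetic cohort generator** (Dirichlet-multinomial, with planted
  core, acquisition waves, decaying transients, mother-only species and a
  solid-food effect) so every stage can be validated against known truth.

## Worked example

```r
library(oralsuccession)

cohort <- simulate_cohort(seed = 7)   # 9 dyads, monthly samples, 0-12 months
res <- run_pipeline(cohort$counts, cohort$metadata,
                    out_dir = "results", seed = 7)
print(res)
```

```
Cohort analysis results
  95 samples retained (0 removed by the <100 filter)
Venn membership (110 species included):
  infant                 55
  toddler                9
  mother                 15
  infant+toddler         0
  infant+mother          0
  toddler+mother         14
  infant+toddler+mother  17
  PERMANOVA (infant/toddler/mother): F = 4.99, p = 0.0001
  convergence: slope -0.0221 per month, p = 5.495e-10 (lmm_satterthwaite)
  succession: 59 species in heatmap, 35 with acquisition calls
```

Reading this output: 17 species are consistently present in infants,
toddlers *and* mothers (the shared core, which holds ~71% of relative
abundance in this cohort); many more species are detected only in one
group (rare taxa that happened to spike in a few samples — the infant-only
count is the most variable region across cohorts); composition differs
significantly between the age groups; the negative convergence slope says
children's communities grow more alike with age; and 35 heatmap species
reach ≥ 75% prevalence in some age interval, in ordered waves.

Individual stages are available as plain functions
(`double_rarefaction_inclusion()`, `prevalence_matrix()`,
`acquisition_intervals()`, `permanova()`, `lme_trend()`,
`event_analysis()`, ...), and a thin command-line front end lives at
`inst/scripts/succession.R` (`simulate` and `run` subcommands).

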