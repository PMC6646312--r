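---
title: "Methods: resampling-based analysis of oral microbiome acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling-based analysis of oral microbiome acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralsuccession)
```

This vignette documents the statistical model behind `oralsuccession`,
the choices made where the design was genuinely open, and what the
package's validation on synthetic cohorts does and does not establish
about real data.

## The data and its two biases

The input is a species-by-sample count table from longitudinal saliva
sampling of mother–child dyads: up to monthly child samples over the
first year, one baseline sample per mother. Two features of such data
break naive prevalence and diversity estimates:

1. **Library sizes vary over two orders of magnitude** (roughly 10² to
   10⁴ sequences per sample). A species "absent" from a 150-read sample
   may simply be undersampled.
2. **Subjects are sampled unequally often** (missed visits are common; in
   a design of 117 scheduled child samples, roughly 6 in 10 are
   collected). Any per-sample statistic over-weights frequently sampled
   children.

Samples under 100 sequences are removed up front
(`filter_low_count_samples()`); below that depth even presence calls are
mostly noise.

## Double-rarefaction inclusion

`double_rarefaction_inclusion()` addresses both biases at once. Per
iteration:

1. rarefy every sample (without replacement — multivariate
   hypergeometric, the same subsampling model as `vegan::rrarefy`) to the
   smallest library size in the analysis set;
2. sum the rarefied counts within each (subject, group) unit;
3. rarefy every combined unit to the smallest combined total, recomputed
   from the iteration's own stage-1 output so the depth is always
   feasible;
4. mark a species "observed" in a group if it is present in at least one
   of that group's units.

The empirical inclusion probability is the observation fraction over
1000 iterations (default), and species at or above 0.95 are group
members. The observation unit — presence in *any* unit of the group — is
the weakest reading consistent with making group-level membership calls;
it is deliberately permissive, and the 95% consistency requirement is
what does the excluding. Both stages rarefy to a *minimum*, so all
samples and all units are compared at equal depth; the stage-1 minimum is
computed after the low-count filter.

One consequence worth knowing: a species carried by a *single* high count
in the smallest sample of a group survives both stages in nearly every
iteration, because the minimum sample is barely subsampled. Inclusion is
therefore "consistently detectable", not "consistently abundant" — this
is faithful to the procedure, and it is why the per-group unique Venn
regions are the most variable ones across replicate cohorts.

RNG: each run takes one seed; iterations consume the stream
sequentially, so results are exactly reproducible. The rarefaction kernel
is a sequential hypergeometric walk in C++ (one `rhyper` draw per
species), which keeps 1000 iterations over a full cohort at about a
second.

## Succession: prevalence and acquisition intervals

Monthly child samples are pooled into 3-month intervals
(`pool_intervals()`), half-open except `[9,12]`, which is closed so that
month-12 samples land in the last bin. Subject-intervals with no samples
are absent and excluded from that interval's denominator; pools under the
rarefaction depth (default 498 sequences) are dropped with a logged
exclusion. Each retained pool is rarefied **once** to the common depth —
a presence heatmap is a single realization, not an average — and
`pooled_presence(n_reps = )` exposes the across-draw presence frequency
for sensitivity analysis. Mothers form one pooled column each, displayed
alongside but never used for acquisition calls.

Prevalence per interval is the fraction of that interval's subjects
positive. Species present in under half of the subjects overall are
dropped (the filter uses pooled-rarefied presence, the same signal as the
heatmap itself, for internal consistency). The acquisition interval is
the **first** interval at ≥ 75% prevalence; a species that later falls
below the threshold keeps its first-crossing call and is flagged
(`drops_below_after`). Rows sort by decreasing overall prevalence, ties
broken by earlier acquisition and then species id, so output order is
reproducible.

## Ordination, tests, convergence

Bray–Curtis dissimilarities are computed on per-sample proportions, NMDS
by `vegan::metaMDS` (Kruskal stress-1, 20 random starts by default;
non-convergence is flagged, not raised). PERMANOVA is implemented
directly from the distance matrix (Anderson's pseudo-F); the p-value uses
the +1-corrected estimator with 9999 random permutations by default, or
exact enumeration of all distinct label assignments when the design is
small enough (≤ 5000 assignments) — the exact mode is what the test
suite validates against, and `vegan::adonis2` serves as an independent
cross-check of the statistic. Shannon diversity uses natural logarithms
(vegan's convention); rarefied diversity and richness are means over 10
independent rarefactions to the smallest relevant library.

Convergence of children toward a shared community profile is measured as
the per-sample distance to the all-children centroid along the **first**
NMDS dimension (the dominant axis of community variation; full-space
Euclidean distance is available as a sensitivity mode), regressed on age
with a linear mixed model, `distance ~ age + (1 | subject)`. The slope's
p-value is a Satterthwaite t-test (lmerTest): with ~9 subjects the
normal-approximation Wald test is visibly anticonservative, and the
Satterthwaite correction keeps the procedure's type-I rate at its nominal
level (verified at 4% over 100 null cohorts in the acceptance suite).
When the random-intercept variance is estimated at zero the model is
singular and the function falls back to OLS with cluster-robust errors by
subject, noted in its `method` field.

Group comparisons of rarefied diversity and richness use Kruskal–Wallis
with Mann–Whitney post-hocs, BH-adjusted within the metric's family of
pairwise comparisons. Exact small-sample branches (Mann–Whitney at
combined n ≤ 12, signed-rank at n ≤ 15, tie-free) match full enumeration
oracles in the test suite.

## Life events

"Immediately pre/post" an event is defined as the latest sample strictly
before the recorded event age and the earliest at or after it; subjects
missing an event age or a sample on either side are excluded with a
recorded reason. Paired metrics (rarefied richness, Shannon, per-species
relative abundance) are tested by Wilcoxon signed-rank; species-level
tests run only on species with nonzero counts in ≥ 25% of the paired
samples (configurable) and are BH-adjusted within that family. Identical
pre/post profiles are a degenerate pairing and report p = 1. The paired
ordination uses the pairs only.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the ground
truth every downstream validation recovers. Its defaults are the study
conditions: 9 dyads, scheduled monthly sampling with 41% missingness
(≈ 69 of 117 child samples collected), one baseline sample per mother,
lognormal library sizes with meanlog = log(2313) and sdlog = 1.122
(matching quartiles near 1068/2313/4850), and a planted community:

- **Core**: 13 named oral taxa with uneven weights summing to exactly
  0.70 of relative abundance at every age and in mothers
  (`target_core_fraction`). A pool of 600 rare background taxa absorbs
  whatever budget the time-varying sets leave unused, so expected
  proportions always sum to 1 while the core fraction stays flat — the
  property the shared-core recovery test asserts.
- **Acquisition waves** of 6/1/7/4 species with onsets at months
  0/3/6/9: weight exactly 0 before onset, then a logistic ramp (rate 4
  per month, midpoint 0.75 months after onset) to a 0.5% plateau. The
  hard zero before onset is what makes "called no earlier than planted
  onset" a meaningful recovery criterion.
- **Transients**: 4 skin/environmental taxa at 0.05% at birth, decaying
  as exp(−1.5·t) (under 1% of their birth level by month 12). They are
  modeled as a fixed exogenous inflow proportion — multinomial noise
  only, no Dirichlet overdispersion — because contamination pressure is
  external to the host community equilibrium. Without this, heavy-tailed
  Dirichlet draws occasionally make a "transient" several percent of one
  early sample, and the inclusion procedure correctly (but unhelpfully
  for validation) admits it.
- **Mother-only anaerobes**: 4 species at 1% each, only in mothers.
- **Solid-food responders**: 8 species at 2% each, appearing in a child
  from that child's solid-food age (drawn per subject from N(6.8, 0.9²)
  months; tooth eruption ages, N(8.7, 2.2²), are recorded but have no
  planted effect — the dissociation the event analysis must reproduce).

Counts are Dirichlet-multinomial with concentration
θ(t) = θ₀·decay^(2t/12), θ₀ = 50; defining between-sample dispersion as
θ^(−1/2) makes `dispersion_decay` exactly the month-0 : month-12
dispersion ratio (default 3, i.e. children start heterogeneous and
converge). Mothers use the month-12 concentration.

**Mechanism isolation.** The convergence and event-dissociation
validations run on truths with waves, transients and (for convergence)
the solid-food effect switched off. With the full structure in place the
*mean* composition changes with age, which is itself a real signal — but
it confounds a null-calibration experiment whose question is "does
distance-to-centroid inference have its nominal type-I rate when only
dispersion varies?". The stationary-mean design isolates the planted
mechanism; the full default structure is exercised by the core/Venn and
succession recoveries.

**What passing does not show.** The generator draws independent
Dirichlet compositions per sample (no within-subject autocorrelation
beyond the planted structure), uses a shared mean profile across
subjects (no persistent personal microbiomes), uniform missingness, and
a step-function event effect. Real cohorts violate all four; the
validations therefore establish correctness of the *machinery* under
known truth, not robustness to every real-world deviation.

## Problem sizes and numerical choices

The validation suite runs at the study's own scale — 9-dyad cohorts,
1000 inclusion iterations — with 20 replicate cohorts for the structural
recoveries and 100 for the convergence and event calibrations; NMDS in
the replicate loops uses 10 random starts (20 in single analyses).
Rarefaction is always without replacement; sampling uses R's RNG
throughout, so a single seed reproduces any analysis exactly.
Tie-breaks, degenerate inputs (all-zero vectors, identical groups,
all-zero paired differences) and non-convergent ordinations all have
defined, tested behavior rather than errors where a result is still
meaningful.

Known limitations: one-factor PERMANOVA only (no multi-factor designs or
strata), no phylogenetic metrics (no tree in scope), and the BIOM reader
is a convenience wrapper requiring the optional biomformat package.
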