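---
title: "Lifespan volumetrics and structural covariance networks in the mouse brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan volumetrics and structural covariance networks in the mouse brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnaging)
```

## The design this package models

`scnaging` analyzes a cross-sectional rodent lifespan design: three age
groups of mice (young, middle-aged, old; roughly ten animals per group,
with one old animal excluded giving a 10/10/9 cohort), each animal
contributing (i) MRI-derived regional brain volumes in mm³, reduced to 32
regions of interest (ROIs), and (ii) a seven-trial Y-maze session whose
goal-arm choices index spatial working memory. Three analysis families sit
on top of that design:

1. **Covariate-adjusted volumetrics.** Pairwise group contrasts
   (young-vs-middle for maturation, middle-vs-old for aging) fit
   `volume ~ group + TBV` per region on the two groups involved, with
   total brain volume (TBV) as covariate. The group indicator codes the
   older group, so a negative t means the older group is smaller.
2. **Brain–behavior association.** A binomial regression of per-animal
   alternation successes on TBV-residualized regional volume over the
   pooled sample; the reported statistic is the signed Wald z for the
   slope.
3. **Structural covariance networks (SCNs).** For each group, the Pearson
   correlation matrix of TBV-residualized volumes, negative entries
   removed, binarized at densities 0.05–0.40 in 1% steps; node degree,
   transitivity, modularity and mean distance compared between groups via
   group-label permutation with a consecutive-density significance rule;
   Walktrap communities and hub cartography describe network organization.

## Multiple-comparison families

Bonferroni–Holm correction is applied within declared families, never
globally: the a-priori volumetric family is 6 tests (3 age-sensitive ROIs —
anterior cingulate area, hippocampal formation, orbital area — × 2 group
pairs, `family = "all"` in `volume_contrast_table()`), the a-priori
association family is 3; brain-wide analyses correct over 32 per
comparison (`family = "per_comparison"`) and over 32 for the single
association family. Where a region appears in both an a-priori and a
brain-wide family it receives two adjusted p-values, one per declared
family; the families are corrected independently.

## Y-maze scoring and its denominator

An alternation is a trial whose goal-arm choice differs from the previous
trial's. With `n` trials only `n − 1` transitions are scorable, so the
default denominator is `trials − 1`: a random chooser then scores 50% in
expectation, which is the chance level the task is usually described
with. The literal "divide by the number of trials" rule is available as
`denominator_rule = "trials"` for comparability, but it puts chance at
`100 × (n−1)/(2n) ≈ 43%` for seven trials; the two conventions disagree
and we default to the one consistent with the 50% chance anchor. Group
differences are tested twice, deliberately: a one-way ANOVA on percent
scores, and a joint Wald χ² from a binomial regression of successes out
of scorable trials on group — the latter because a 7-trial proportion is
bounded and non-normal. Whether such proportion outcomes are better
served by a quasi-binomial variance is unsettled; the association stage
exposes `dispersion = "quasibinomial"` for the dispersion-adjusted Wald
statistic, with plain binomial as the default.

A note on reporting conventions: association tables in this field often
print the signed Wald statistic under a χ² heading (a literal χ² cannot
be negative). We expose the signed Wald z and label it `stat`.

## Network construction choices

Several knobs in SCN analysis are conventions rather than estimates; all
are explicit arguments with reported defaults:

* **Edge count at density d** is `round(d × n(n−1)/2)` with *half-up*
  rounding (`round(24.8) = 25` edges at 5% density on 32 nodes). The
  rounding rule is rarely stated in the literature; fixing it makes edge
  sets bit-reproducible.
* **Ties** at the threshold boundary are broken by lexicographic
  region-name-pair order. Ties have probability zero for continuous
  volumes but arise in tests and degenerate inputs; a deterministic
  tie-break keeps the density sweep nested (the edge set at density d is
  a subset of the edge set at any d′ > d).
* **Negative correlations are removed before thresholding**, so a zeroed
  entry can never become an edge regardless of how sparse the positive
  tail is. If fewer positive entries exist than the density requests, the
  network is built from all of them and a warning records the shortfall.
* **Mean distance** averages shortest paths over reachable pairs only,
  excluding disconnected pairs rather than treating them as infinite —
  the default of the igraph library and the only finite choice at low
  densities. Profiles where a network has no edges at all report a
  missing value, which the run rule treats as non-significant.
* **Walktrap** runs with walk length 4 (the algorithm's common default;
  exposed as `steps`/`walktrap_steps`). Isolated nodes become singleton
  communities appended after clustering the non-isolated subgraph.
* **Hub thresholds**: a node is a hub when its within-community degree
  z-score is ≥ 1.0; hubs split into provincial (participation
  coefficient < 0.30) and connector (≥ 0.30). The literature says only
  "high" and "low"; these cutoffs are named, overridable constants
  (`z_hub_min`, `p_connector_min`) and are echoed in every cartography
  output. Because fixed cutoffs and per-community top-ranking can
  disagree, `cartography()` also reports the most prominent provincial
  (highest z) and connector (highest P) hub per community.

## Permutation inference

The exchangeable unit under the null of "no group difference" is the
animal, so permutations shuffle animals' group labels within the pooled
two-group sample, preserving group sizes. One relabeling drives one full
density sweep, preserving the strong dependence between neighbouring
densities that the consecutive-threshold rule relies on. TBV
residualization is fit once on the pooled sample and not refit per
relabeling: the adjustment is label-free, so refitting would only add
computation, not change results. Modularity is recomputed per relabeling
with a fresh Walktrap partition — the statistic is "maximum-modularity of
the relabeled network", not the observed partition's score on relabeled
data.

Empirical p-values use the add-one two-tailed rule on absolute
differences, `p = (1 + #{|null| ≥ |obs|}) / (1 + N)`, which cannot reach
zero and is well-defined for the discrete nulls that integer-valued
degree differences produce. Significance requires p < α at `run_min = 5`
or more adjacent densities; run intervals are reported in the
"(23–40% density)" style.

**What the run rule does and does not control.** Our null simulations
(see the acceptance suite and `scripts/acceptance.R`) show the
per-density empirical test holds its level exactly (rejection ≈ 10/201 at
200 permutations). The run rule then cuts the family-wise rate across the
36 densities far below the naive "significant anywhere" rate (≈ 0.34 →
≈ 0.08–0.10 in 200-replicate null simulations), but *not* strictly below
the per-density α itself: because adjacent densities are almost perfectly
dependent, a single lucky configuration tends to persist ≥ 5 densities,
so the family-wise rate approaches the marginal level from above. The
rule should be read as a strong, dependence-exploiting filter, not an
exact FWER guarantee.

## The synthetic cohort generator

Real MRI-derived volume tables for such designs are rarely redistributable,
so the generator is a first-class module whose defaults *are* the study
conditions: groups of 10/10/9, 32 ROIs with the standard hierarchy's
names, 7 trials per animal. Its free parameters, which no design document
pins down, were chosen once at field-realistic values:

* `tbv_mean = 450`, `tbv_sd = 18` mm³ — adult C57BL/6 whole-brain volumes
  by deformation-based morphometry cluster around 430–470 mm³;
* baseline region volumes are deterministic fractions of TBV spanning a
  modest size range and summing to 95% of TBV, so every region co-scales
  with brain size and the TBV covariate genuinely matters (omitting it
  biases contrasts);
* `noise_sd = 0.5` mm³ of residual volume noise, with planted group
  shifts expressed in units of this SD;
* residual noise is drawn from a block-constant correlation matrix over
  four planted communities of eight regions (`within_community_r = 0.5`,
  `between_community_r = 0.10`) — the simplest structure Walktrap can
  provably recover, and positive-definiteness is checked at generation
  with an error naming the offending block parameters;
* behavior is simulated trial by trial (a Bernoulli alternation per
  post-first trial), not as a beta-drawn proportion, so the scoring
  denominator question is actually testable; the logit of the alternation
  probability is `Σ slope × standardized residual volume`, putting chance
  exactly at 0.5 when no link is planted;
* an optional `attenuation` block multiplies one region's within-community
  correlations by a factor in one group, planting a node-level
  connectivity change for the degree comparison to find (a factor of −1
  flips the sign, and negative-edge removal then guarantees the loss).

What the generator does *not* emulate: registration and segmentation
error, hemispheric asymmetries, non-Gaussian volume distributions,
age-dependent variance heterogeneity, and any nonlinear TBV allometry.
Passing tests therefore certify the statistical machinery under the
assumed model, not robustness of the conclusions to real-data artifacts.

## Numerical and degenerate-input conventions

* Residualization refuses constant TBV (rank-deficient design) and
  requires ≥ 3 animals; contrasts require ≥ 3 animals per group,
  covariances ≥ 4, permutation comparisons a pooled sample of ≥ 8.
* A region with zero volume variance (or zero residual variance) within a
  group is an error naming the region, not a silent NaN.
* Logistic fits that separate or hit the boundary (e.g. an all-zero
  success column) are flagged non-convergent; no Wald statistic or
  p-value is fabricated for them, and Holm families shrink accordingly.
* A group ANOVA with zero within-group variance reports a degenerate
  result instead of propagating NaN.
* Walktrap on an empty network returns all-singleton communities with
  Q = 0 and a warning; transitivity of a triple-free graph is 0.

## Problem sizes used in the shipped checks

The test and acceptance suites run the generator at the design sizes
above. Simulation counts were fixed in advance of measurement at sizes
that give stable Monte-Carlo error on a single CPU: 1000 replicate null
cohorts for contrast type-I error, 500 for permutation-level checks at
200 permutations per sweep, 500/100/200 replicates for the three
parameter-recovery checks (with 1000 permutations for the degree power
check, whose planted effect — sign-flipping decorrelation of one region in
one group under within-community r = 0.9 — was frozen after a pilot run).
The full reference analysis (5000 permutations for a-priori and global
comparisons, 1000 for brain-wide degree) is the shipped default of
`run_config()`.

## Known limitations

* Pairwise contrasts fit each group pair separately (as the design
  prescribes) rather than one three-group model; no trend or nonlinear
  age modeling is attempted.
* Only unweighted, unsigned networks are implemented; negative
  covariance structure is discarded by construction, and weighted or
  signed metrics, small-world and rich-club statistics are out of scope.
* The run rule's family-wise behavior is characterized empirically, not
  analytically (see above).
* The hemisphere-averaging step expects `_left`/`_right` suffixed column
  pairs; other laterality encodings must be renamed upstream.
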