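---
title: "Partitioning scale-dependent biodiversity responses to land management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning scale-dependent biodiversity responses to land management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalediv)
```

## The problem

Whether grazing (pasture) or mowing (meadow) supports more biodiversity in
seminatural grasslands depends on the spatial grain at which diversity is
measured. A management type can depress richness within a 1 m² subplot while
increasing it at the pooled site scale, or vice versa, because management acts
on three distinct components of community structure: the **density of
individuals**, the **species-abundance distribution** (evenness), and the
**intraspecific spatial aggregation** of individuals among subplots. `scalediv`
implements a two-scale partitioning analysis that separates these components,
quantifies management effects as log-response ratios, attaches
scale-appropriate significance tests, and classifies each response's scale
dependence. A hierarchical community simulator with independent knobs for the
three components supports calibration and power analysis.

The sampling hierarchy mirrors a typical multi-site grassland survey: five
sites, up to three 10 m × 10 m plots per management type per site, ten 1 m²
subplots per plot. The subplot is the α-scale; all subplots of a
site-management group pooled together form the γ-scale; β-diversity is their
multiplicative ratio.

## Data model and preparation

A `community_table` holds a subplot × species abundance matrix plus the
nested sample metadata. Two abundance conventions are supported:

* **Counts** (e.g. OTU reads). Rare OTUs can be removed with
  `filter_rare_otus()`, which keeps a taxon only if it occurs *more than*
  `min_count` times (strictly) in at least `min_sample_fraction` of the
  samples. Defaults are 5 reads and 1 %. Two deliberate readings are baked in:
  the count threshold is per sample (the usual phyloseq-style prevalence
  filter), not a dataset-wide total; and the sample threshold is
  `ceiling(fraction × n_samples)`, so it can never be zero.
* **Percent cover** (plants). Rarefaction and encounter probabilities need
  discrete individuals, so `cover_to_counts()` rounds cover to integer
  pseudo-individuals, with any positive cover below 0.5 % mapped to 1 so that
  presence is never destroyed. This discretisation is a package convention;
  nothing in the estimators depends on the units being "individuals" beyond
  discreteness.

All-zero taxa are retained (and logged) by the readers; subplots with fewer
than two individuals are kept for N and S but excluded, with a warning, from
the rarefaction base and the evenness metrics, for which they are undefined.

## The metrics

For an abundance vector with per-species counts $N_i$ and total $N$:

* **Rarefied richness** $S_n = \sum_i \left[1 - \binom{N-N_i}{n}/\binom{N}{n}\right]$,
  the expected species count in a uniform subsample of $n$ individuals drawn
  without replacement. Binomial coefficients are evaluated with `lchoose`, so
  totals of $10^7$ reads are handled without overflow. $n$ is the **minimum
  subplot total at the site across both management types**
  (`rarefaction_base_n()`), shared between groups so that density differences
  are controlled away; at the γ-scale the reported $S_n$ uses $n$ times the
  number of subplots in the group.
* **PIE**, the probability of interspecific encounter:
  $\frac{N}{N-1}\left(1-\sum_i (N_i/N)^2\right)$, computed in the equivalent
  integer form $(N^2-\sum_i N_i^2)/(N(N-1))$ which is exact in double
  precision. It is the probability that two individuals drawn without
  replacement differ in species, and the slope at the base of the
  individual-based rarefaction curve.
* **$S_{PIE}$** $= 1/(1-\mathrm{PIE})$, the number of equally abundant species
  with the same encounter probability — an evenness-weighted effective
  species number emphasising common species (the order-2 Hill number in the
  large-$N$ limit).
* **β-diversity**: Whittaker's multiplicative partition $\gamma/\bar\alpha$
  for $S$, $S_n$ and $S_{PIE}$. Inside `beta_partition()` the γ-scale $S_n$
  is recomputed at the *same* $n$ as the subplots, so that β-$S_n$ isolates
  spatial aggregation from density and abundance-distribution effects.

One finite-sample subtlety is worth stating because it shapes the test
expectations: with the without-replacement estimators, pooling $k$ identical
subplots gives the γ community $k$ times the individuals, so β-$S_n$ and
β-$S_{PIE}$ for perfectly homogeneous groups sit slightly *below* 1 (by
$O(1/N)$) and converge to 1 as totals grow. Only the uncorrected,
proportion-based estimators would give exactly 1; the package keeps the
corrected forms, which are the standard ones for this analysis.

## Inference

Effects are summarised as **log-response ratios**
$\ln(x_{\text{pasture}}/x_{\text{meadow}})$, meadows as reference.

* **α-scale**: one-way ANOVA on the per-subplot values (two groups, so
  $F = t^2$ of the pooled-variance t-test). Degenerate inputs with no
  variance and equal means return $p = 1$; an optional label-permutation p
  for the same F statistic is available.
* **γ- and β-scale**: there is one value per management type, so a
  **permutation test** is used: subplots are randomly reassigned to the two
  management labels preserving group sizes (199 permutations by default), the
  group metrics are recomputed, and the two-sided p-value follows the add-one
  rule $p = (1+\#\{|LRR^*|\ge|LRR|\})/(n_{perm}+1)$, making $1/200 = 0.005$
  the smallest reportable value and keeping the test valid for any statistic.
  Ties count as extreme. Permutation at the whole-plot level is available via
  `permute = "plot"` for designs where the plot is the more defensible
  exchangeable unit; the subplot-level default matches the pooled-data
  description of the analysis and gives the null far more resolution with
  only 2–4 plots per group. The statistic defaults to the LRR; the raw
  difference is available via `statistic = "diff"`.
* **Design balancing**: when plot numbers differ between management types,
  the larger group is repeatedly restricted to as many whole plots as the
  smaller group has — every one of the $\binom{P_{large}}{P_{small}}$
  combinations, capped at 200 uniformly drawn distinct subsets. Balancing
  operates on whole plots (keeping all their subplots) because the replicate
  counts of the unbalanced field designs (3-vs-1 plots → 3 replicates,
  4-vs-2 → 6) are only reproduced by plot-level enumeration. Replicate LRRs
  are combined by their arithmetic mean and replicate p-values by the plain
  **harmonic mean** $k/\sum p_i^{-1}$ — used here as an averaging rule for
  dependent replicate tests, not as Wilson's asymptotically exact
  harmonic-mean-p procedure; the replicates share most of their data, so a
  combination rule, not an independence-based combination test, is what is
  defensible. For balanced designs the single identity replicate makes the
  standardized analysis equal the plain one exactly.
* **Classification**: each metric's α/γ pair of effects is classified at
  $p < 0.05$ into `qualitative_reversal` (both significant, opposite signs),
  `alpha_only`, `gamma_only`, `consistent_both`, or `none`;
  `summarize_quadrants()` tallies the categories and the reversal fraction.
  No multiple-testing correction is applied across sites or metrics — each
  site × group comparison is reported as its own test.

All randomness flows from one master seed per analysis; replicate permutation
seeds are drawn from it, so any run is exactly reproducible and two runs with
the same configuration write byte-identical outputs (the on-disk manifest
deliberately omits the timestamp).

## The simulator

`simulate_experiment()` draws a hierarchical dataset in the survey design with
three independent component knobs:

* **Density**: subplot totals are Poisson(`density_lambda`), so density and
  richness effects decouple naturally (no fixed-N constraint).
* **SAD / evenness**: one standard-normal deviate $z_i$ per species per site,
  shared between management groups; a group's regional relative abundances
  are $\propto \exp(\sigma z_i)$. `sad_sigma = 0` is a perfectly even pool;
  larger σ is less even. Sharing $z$ means a treatment multiplier on σ
  changes evenness without changing the species pool or the abundance ranks —
  the within-site comparison the analysis is built around.
* **Aggregation**: each subplot's composition is
  Dirichlet(`aggregation_theta` × p) around the regional SAD, then
  multinomial. Small θ concentrates species into subsets of subplots
  (aggregation); θ ≥ 10⁸ shortcuts to exactly the regional composition.
  This Dirichlet-multinomial formulation maps directly onto β-$S_n$ and keeps
  the simulator fast; it is not a spatially explicit point process.

Treatment multipliers (`density_mult`, `sigma_mult`, `theta_mult`) apply to
the pasture group only; all multipliers at 1 give an exact null in which the
groups are exchangeable by construction.

Defaults (λ = 100 individuals per subplot, 50-species pool, σ = 1, θ = 5,
10 subplots per plot) describe a moderately uneven, moderately aggregated
grassland at a density where a 1 m² subplot yields on the order of 100
countable units — the regime the estimators are designed for.

One coupling is **inherent, not a simulator artefact**: intraspecific
aggregation necessarily reduces within-subplot evenness. If subplot
composition $q$ has mean $p$ and between-subplot variance rises (smaller θ),
then $E[\sum q_i^2] = \sum p_i^2 + (1-\sum p_i^2)/(\theta+1)$ rises, so the
α-scale $S_{PIE}$ falls — whichever mechanism generates the aggregation.
An aggregation-only treatment therefore moves α-scale evenness as well as
β-$S_n$; the validation suite documents this rather than pretending the
components are fully orthogonal. $S_{PIE}$ comparisons across scales are
unbiased except under strongly altered aggregation, and users should read
α-$S_{PIE}$ contrasts in that light.

## What the simulation does and does not emulate

The generator reproduces the design's nesting, unbalanced plot counts,
realistic subplot totals, uneven SADs, and tunable spatial aggregation. It
does **not** emulate: explicit spatial coordinates or dispersal (aggregation
is exchangeable across subplots, with no distance decay); plot-level random
effects (subplots within a plot are no more similar than subplots across
plots of the same group, so the subplot-permutation null is exactly true in
simulation — field data with plot-level structure may make it liberal, which
is why the plot-level permutation option exists); taxonomic error,
compositionality of relative reads, or sequencing depth variation in OTU
tables; and temporal dynamics. Green tests therefore certify the estimators
and the inferential machinery under the stated sampling model, not the
field-data properties outside it.

## Numerical choices and problem sizes

* `lchoose`-based rarefaction: stable to at least $N = 10^7$; exactness
  against brute-force subset enumeration is verified for every abundance
  multiset with $N \le 8$ at tolerance $10^{-12}$.
* PIE in integer form: bitwise-equal to exhaustive ordered-pair enumeration
  for 500 random vectors with $N \le 50$.
* Null calibration: 1,000 simulated null datasets (λ = 100, 50 species,
  σ = 1, θ = 5, two plots of ten subplots per group), 199 permutations each;
  the rejection rate at 0.05 is required to fall in [0.03, 0.07] for each
  γ-scale metric.
* Component recovery: 20 replicate simulations per scenario at λ = 200,
  100 species, 30 subplots per group — sizes at which Monte-Carlo error on a
  mean LRR is well under 0.05 while the whole suite stays under a minute.
* Ties in permutation tests are compared with a $10^{-12}$ absolute guard;
  degenerate permutation draws (undefined metric) are resampled with a hard
  cap of 10 × `n_perm` attempts.

## Known limitations

* The harmonic-mean combination is an averaging convention for strongly
  dependent replicates; it has no exact size guarantee.
* β estimates inherit the $O(1/N)$ finite-sample bias described above;
  comparisons of β between groups (the LRR) cancel most of it, absolute β
  values near 1 should not be over-interpreted.
* The α-scale ANOVA treats subplots as independent replicates; with strong
  plot-level structure, fit the plot as the unit (or use the plot-level
  permutation) instead.
* With 2–4 plots per group, plot-level permutation has very coarse p-value
  resolution; this is a property of the design, not the implementation.
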