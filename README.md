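# scalediv

Two-scale partitioning of grassland biodiversity responses to land management
(pasture vs. meadow).

Whether grazing or mowing supports more biodiversity depends on the spatial
grain of measurement: management can act on the density of individuals, on
community evenness (the species-abundance distribution), or on the spatial
aggregation of species among subplots, and these components leave different
fingerprints at the 1 m² subplot scale (α), the pooled site scale (γ), and in
the turnover between them (β). `scalediv` implements the full analysis for
ecologists comparing management types in nested designs — and for
methodologists who want a calibrated, simulation-backed version of it:

* **Metrics** — for each site × management group: abundance `N`, richness
  `S`, individual-based rarefied richness
  `S_n = Σ_i [1 − C(N−N_i, n)/C(N, n)]` at the site-wide minimum subplot
  total `n`, Hurlbert's probability of interspecific encounter
  `PIE = N/(N−1) · (1 − Σ_i (N_i/N)²)`, its effective species number
  `S_PIE = 1/(1 − PIE)`, and Whittaker's multiplicative partitions `β_S`,
  `β_S_n`, `β_S_PIE = γ/ᾱ` (β-`S_n` at the same `n` for both scales, which
  isolates spatial aggregation).
* **Inference** — effects as log-response ratios `ln(pasture/meadow)`;
  one-way ANOVA on subplot values at the α-scale; permutation tests
  (199 label reshuffles, add-one rule, two-sided on |LRR|) at the γ- and
  β-scales; whole-plot resampling to balance unequal designs, with replicate
  p-values averaged by their harmonic mean; classification of each response
  as a qualitative reversal, single-scale effect, consistent effect, or null.
* **Simulation** — a hierarchical community generator (lognormal SAD,
  Poisson densities, Dirichlet-multinomial aggregation) with independent
  treatment multipliers per component and exact-null configurations, used to
  calibrate the tests and verify component recovery.
* **Data handling** — long/wide delimited readers and writers, percent-cover
  discretisation, and the `>5` reads in `≥1%` of samples prevalence filter
  for OTU tables.

## Worked example

Simulate one site in the survey design (3 plots × 10 subplots per management
type, 50-species pool, about 100 individuals per subplot) where pasture
management reduces evenness (SAD sigma × 1.5) but leaves density untouched,
then run the full analysis:

```r
library(scalediv)

cfg <- simulation_config(n_sites = 1, plots_per_group = c(pasture = 3, meadow = 3),
                         subplots_per_plot = 10, species_pool = 50,
                         density_lambda = 100, aggregation_theta = 5,
                         sigma_mult = 1.5, seed = 2020)
tab <- simulate_experiment(cfg)$table
res <- run_site_taxon_analysis(tab, "site01", taxon_group = "grassland",
                               n_perm = 199, seed = 1)
res$effects[, c("metric", "scale", "lrr", "p_value")]
#>        metric scale      lrr p_value
#> 1           N alpha -0.00834 0.76979
#> 2           S alpha -0.16705 0.00336
#> 3         S_n alpha -0.15650 0.00367
#> 4       S_PIE alpha -0.08592 0.36755
#> 5           N gamma -0.00834 0.79000
#> 6           S gamma -0.15763 0.01000
#> 7         S_n gamma -0.16376 0.00500
#> 8       S_PIE gamma -0.60699 0.00500
#> 9    beta_S_n  beta -0.09178 0.25000
#> 10 beta_S_PIE  beta -0.52107 0.00500
```

Reading the table: density is untouched (`N`: LRR ≈ 0, not significant), but
the evenness treatment depresses richness at both scales (`S`, `S_n`:
LRR ≈ −0.16, p < 0.01) and hits the evenness metric hardest where rare-species
accumulation matters — `S_PIE` drops strongly at the γ-scale
(LRR = −0.607, p = 0.005, the smallest value 199 permutations can report)
while staying non-significant at the α-scale. The classification makes the
scale structure explicit:

```r
res$classification[, c("metric", "category", "lrr_alpha", "lrr_gamma")]
#>   metric        category lrr_alpha lrr_gamma
#> 1      N            none  -0.00834  -0.00834
#> 2      S consistent_both  -0.16705  -0.15763
#> 3    S_n consistent_both  -0.15650  -0.16376
#> 4  S_PIE      gamma_only  -0.08592  -0.60699
```

## The analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin script
over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # five-site survey (null + managed), TSV + truth JSON
Rscript analysis/02_metrics.R     # two-scale metrics per site x management
Rscript analysis/03_inference.R   # full pipeline: effects + classification
Rscript analysis/04_summarize.R   # quadrant/reversal tally
```

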