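# ringcarbon

Retrospective reconstruction of individual-tree lifetime carbon
accumulation from annual tree-ring width series.

Long-term monitoring plots rarely cover a tree's whole life, so claims
about how *old* trees accumulate carbon are hard to test. Tree-ring series
measured on stem discs are a retrospective record of the entire lifetime:
each ring is one year of diameter growth. `ringcarbon` turns such series —
for tropical species with anatomically distinct annual rings, such as
*Cedrela odorata*, *Goupia glabra* and *Hymenaea courbaril* from Suriname
wet forest — into annual carbon-accumulation trajectories and asks, with
nonparametric statistics, whether growth is sustained, fluctuating,
plateauing or declining with age, and what share of lifetime carbon is
fixed late in life.

The package is aimed at dendrochronologists and forest-carbon ecologists.
It covers the full chain:

1. **I/O** — Tucson/RWL decadal files and long-form tables
   (`read_rwl()`, `write_rwl()`, `read_series_table()`), with wedge
   (locally absent) rings encoded as width 0.
2. **Mean series & diameter** — per-tree averaging of ≥ 2 cross-dated
   radii with wedge-year exclusion (`mean_tree_series()`), pairwise
   cross-dating coherence checks (`crossdate_check()`), and diameter
   reconstruction `D(t) = 2 Σ w(i) / 10` (`reconstruct_diameter()`).
3. **Carbon model** — the pantropical height-free allometry

   ```
   AGB = exp{ −1.803 − 0.976 E + 0.976 ln ρ + 2.673 ln D − 0.0339 [ln D]² }
   ```

   with wood density ρ (g cm⁻³), diameter D (cm) and a site environmental
   stress factor E (`agb_chave()`); carbon stock = carbon fraction × AGB
   (default 0.471); annual accumulation is the year-over-year difference
   (`carbon_trajectory()`); lifetime-quartile shares via
   `quartile_shares()`.
4. **Inference** — exact-binomial Cox–Stuart trend test (`cox_stuart()`),
   Pettitt change-point test (`pettitt()`), Dunn's tie-corrected pairwise
   rank test (`dunn_test()`), one-way ANOVA with Holm-adjusted pooled-SD
   t-tests (`compare_species()`), and a deterministic four-archetype
   growth-pattern classifier (`classify_pattern()`): sustained increase,
   increase with depression, plateau, rise then decline.
5. **Synthetic cohorts** — a seeded generator (`simulate_cohort()`)
   emulating the published three-species study design (61 trees, ages
   84–255 y, final diameters 36.7–99.2 cm, ≥ 2 radii per tree, wedge
   rings, multiplicative lognormal AR(1) ring-width noise) with a
   ground-truth ledger, so the whole pipeline is testable without field
   data, which were never deposited.

## Worked example

```r
library(ringcarbon)

cohort <- simulate_cohort(default_cohort_config(seed = 1))
report <- run_pipeline(cohort$trees)
print(report)
#> <run_report> 61 trees, 3 species; alpha = 0.05
#>   significant increasing cumulative-carbon trend: 61 of 61 trees

report$summary$stock[, c("species","n_trees","age_mean","diameter_mean","carbon_mean")]
#>       species n_trees age_mean diameter_mean carbon_mean
#> 1   C.odorata      20      128          50.3         642
#> 2    G.glabra      21      162          62.0        1977
#> 3 H.courbaril      20      187          73.3        3184

table(report$tests$pattern_carbon)
#> increase_with_depression        rise_then_decline       sustained_increase
#>                        6                        1                       54
```

Mean lifetime-quartile carbon shares for this cohort rise from ~1.5 % in
the first quarter of life to 57–60 % in the last quarter: these synthetic
trees, like the published cohort they emulate, fix most of their carbon
late in life (the convex diameter–biomass allometry concentrates carbon
accumulation at large diameters even for steady diameter growth).

A shell entry point with `simulate`, `run` and `report` subcommands is
installed at `inst/scripts/ringcarbon`; cohort configurations are plain
YAML (`read_cohort_config()`).

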