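# metabofun

Comparative analyses linking **functional gene content** to
**mass-specific metabolic rate** and **maximal lifespan** across
organisms, from prokaryotes to mammals.

Metabolic rate *B* scales with body mass *M* as a power law,
*B* ∝ *M*^α, so the mass-specific rate *q* = *B*/*M* follows
*q* ∝ *M*^(−β) with β = 1 − α. Whether genomes add information beyond
this mass scaling is contested: genome *size* correlates with little once
mass is controlled. metabofun implements a different measure — the
**proportion of genes in a functional category** (category gene count
divided by the genome's total gene count), with special attention to
**oxic genes**: genes linked to at least one metabolic reaction that
occurs in the presence of oxygen, called by intersecting per-genome
gene–reaction annotations with a curated oxic-reaction list (KEGG "R"
numbers / EC numbers).

The statistical core is the Spearman rank correlation and its
body-mass-controlled first-order partial,

    r_xy.z = (r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²)),

computed on tie-averaged ranks with t-approximation p-values (exact
permutation enumeration for n ≤ 8), plus a category screen sorted by the
partial coefficient, temperature corrections of *q* (Q10-style doubling
per 10 °C and Boltzmann–Arrhenius with activation energy E in eV), and
ordinary least-squares estimation of β on log10 scales.

The package is tidyverse-native: functions take data frames first and
return tibbles, fitted objects have `tidy()`/`glance()` methods, and
results have ggplot2 builders (`plot_screen()`, `plot_oxic_scatter()`,
`autoplot()`).

## What's inside

| Stage | Functions |
|---|---|
| Annotation IO | `parse_kgml()`, `parse_brite_keg()`, `read_gene_lengths()`, `load_oxic_reactions()` |
| Profiling | `call_oxic_genes()`, `compute_profile()`, `profiles_wide()` |
| Traits | `read_trait_table()`, `convert_units()`, `genus_average()`, `select_representative()`, `collapse_to_genus()` |
| Temperature | `q10_style_correct()`, `boltzmann_correct()`, `filter_temperature_eligible()` |
| Rank statistics | `spearman()`, `partial_spearman()`, `correlation_screen()`, `subgroup_partial()` |
| Allometry | `fit_power_law()` |
| Synthetic panels | `panel_config()`, `generate_panel()`, `write_fixture_files()`, `read_fixture_profiles()` |
| Orchestration | `run_pipeline()`, `run_metabolic_analysis()`, `run_lifespan_analysis()` |

Because trait tables with matched, redistributable genome annotations at
this breadth do not exist publicly, the package ships a first-class
synthetic-panel generator that plants known effects (mass scaling,
mass–genome link, oxic effects on rate and lifespan, pure-noise decoy
categories) and realises every proportion as integer gene counts, so
on-disk KGML/`.keg`/FASTA fixtures round-trip through the parsers
*exactly*. See the vignette (`vignettes/functional-gene-content.Rmd`)
for the model, defaults, and what the generator does and does not
emulate.

## A worked example

```r
library(metabofun)

panel  <- generate_panel(panel_config(), seed = 11, build_annotations = FALSE)
report <- run_pipeline(panel$traits, panel$profiles)
report
#> Comparative functional-genome analysis (101 organisms analysed)
#>   Allometry: q ~ M^(-0.012 +/- 0.004), n = 101
#>   q_vs_genome_size             r = -0.260  p = 0.00874  (n = 101)
#>   q_vs_genome_size_given_mass  r = -0.075  p = 0.458  (n = 101)
#>   q_vs_oxic                    r = +0.348  p = 0.000364  (n = 101)
#>   q_vs_oxic_given_mass         r = +0.601  p = 3.84e-11  (n = 101)
#>   Screen: 4 of 31 categories retained at alpha = 0.05; top: Oxic metabolism
#>   Lifespan vs oxic | mass:     r = -0.547  p = 0.0231  (n = 18)
```

Reading the output: the simple genome-size correlation with *q* is
negative (−0.26) but vanishes once body mass is held constant (−0.075,
p = 0.46) — genome size carries no signal beyond mass. The oxic gene
proportion does the opposite: its association with *q* **strengthens**
under mass control (+0.60, p ≈ 4e−11) because the planted effect is
direct, and the category screen ranks "Oxic metabolism" first among 31
categories. The lifespan analysis on the mammal/bird subset shows the
planted negative mass-controlled oxic–lifespan association.

```r
glance(fit_power_law(panel$traits$mass_g, panel$traits$q_W_per_g))
#> # A tibble: 1 × 5
#>     beta std.error intercept r.squared     n
#>    <dbl>     <dbl>     <dbl>     <dbl> <int>
#> 1 0.0116   0.00362     -1.88    0.0945   101
```

(The default panel's fitted exponent is shallower than the planted
β = 0.035 because the mass-linked oxic effect partly offsets the direct
scaling; see the vignette.)

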