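# xsci — cross-species spinal cord injury transcriptome concordance

`xsci` compares injury-induced transcriptional responses across species to
separate what is conserved from what is not. The motivating setting is
traumatic spinal cord injury: rodents respond with scarring, salamanders
(axolotls) regenerate, and a gene whose injury response points the same
way in every species is a different kind of therapeutic candidate than
one whose response flips sign only in the regenerating species. The
package implements the whole comparison as a tested, tidyverse-native
pipeline that runs end-to-end on synthetic data with planted ground
truth, and equally on user-supplied expression tables.

## What it computes

For each two-arm study (injured vs. control, log2 expression), the
empirical-Bayes **moderated t**:

    s̃²_g = (d₀·s₀² + d·s²_g) / (d₀ + d)
    t_g  = log2FC_g / (s̃_g · √(1/n₁ + 1/n₂)),   df = d₀ + d

with (d₀, s₀²) estimated by moment-matching on log s², BH-adjusted
p-values, 95% confidence intervals, and probeset→gene collapsing by
highest average expression. Gene tables are harmonized onto mouse
orthologs (rank-1 candidates; salamander resolved through a
salamander→human→mouse chain), intersected across species, and each
ortholog significant in **every** study (p_adj ≤ 0.05) is classified by
its fold-change sign pattern as `consistent`, `opposite_outgroup`
(salamander flips), or `other`. The classes partition the significant
set. Each class is then tested for gene-set over-representation with the
hypergeometric upper tail and scored as ES = −log₁₀(p_adj); amino-acid
conservation is quantified by percent identity and Poisson-corrected
distances d = −ln(1 − p) with pairwise deletion, from which a
neighbor-joining tree is built; interaction edge lists are filtered at
confidence ≥ 0.4 with singleton removal and degree-sorted node order; and
immunostain images are quantified as threshold/binarize/area-fraction
with a two-way ANOVA (group × region) and Holm–Šídák per-region
comparisons.

## Worked example

```r
library(xsci)

cfg <- run_config(sim = simulation_config(seed = 42, n_genes = 300),
                  seed = 42)
run <- run_pipeline(cfg)
run
#> xsci pipeline run (seed 42, alpha 0.05, outgroup salamander)
#> studies: rat_a, rat_b, mouse_a, sal_a
#> significant orthologs: 56 (consistent 29, opposite 27, other 0)
#> planted: consistent 30, opposite 30
#> conservation: 6 taxa, mean identity 82.0%
#> network: 56 nodes, 129 edges
```

The simulation planted 30 consistent and 30 opposite genes among 300; the
pipeline recovered 29 and 27 of them as significant in all four studies
with the correct sign pattern, and none were misclassified into `other`.
The per-study fits expose their shrinkage prior through `glance()`:

```r
glance(run$de$rat_a$fit)
#> # A tibble: 1 × 8
#>   study_id species n_probesets n_injured n_control    d0 s0_sq df_total
#> 1 rat_a    rat             621         4         4  63.9 0.255     69.9
```

i.e. 621 probesets, and ~64 prior degrees of freedom augmenting the 6
residual df of a 4-vs-4 design. Enrichment on the consistent class ranks
the planted set first:

```r
head(run$enrichment$consistent, 1)
#>   term_id            k  K  n   N        p     p_adj    es
#> 1 PLANTED_CONSISTENT 24 24 29 300 6.71e-31 2.15e-29  28.7
```

(24 of the 24 planted members fall in the 29-gene query; ES is
−log₁₀ of the adjusted p.) Individual stages are plain functions over
data frames — `fit_moderated_t()`, `collapse_probesets()`,
`map_to_reference()`, `intersect_and_classify()`, `hypergeom_enrich()`,
`poisson_distance()`, `neighbor_joining()`, `filter_network()`,
`area_fraction()`, `two_way_anova_holm_sidak()` — each with `tidy()` /
`glance()` / `autoplot()` methods where a fitted object is returned. See
`vignettes/cross-species-concordance.Rmd` for the methods account.

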