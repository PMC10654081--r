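# pitmudr

Microbial biogeography analysis for the clay lining ("pit mud") of
strong-flavor Baijiu fermentation cellars — and for any microbiome survey
organized along an age-by-region design. Starting from an OTU count table,
a rooted phylogeny, taxonomy and sample metadata (cellar-age groups
Aa < Ab < Ac < Ad, longitude groups La–Ld), the package answers three
questions a pit-mud ecologist asks:

1. **How do diversity and composition change with cellar age?**
   Rarefaction, Chao1 / Shannon / Pielou with Tukey HSD group tests and
   age-trend regression, Bray–Curtis and normalized weighted UniFrac
   distances, NMDS ordination, PERMANOVA variance partitioning, and
   per-group taxon overlap (Venn-style) at any taxonomic rank.
2. **Is community assembly stochastic or deterministic?** The
   phylogenetic null model
   βMNTD = 0.5[Σᵢ f_{ik} min Δ_{i,jm} + Σᵢ f_{im} min Δ_{i,jk}] with
   βNTI = (βMNTDobs − mean βMNTDnull) / sd(βMNTDnull) against 999 tip
   shuffles; βNTI > 2 → heterogeneous selection, βNTI < −2 → homogeneous
   selection, |βNTI| ≤ 2 → stochastic, with per-age-group process
   fractions. The kernel is compiled, so hundreds of samples at ~10⁰⁰⁰
   reads are minutes, not hours.
3. **How do co-occurrence networks restructure with age?** Spearman
   screening (|r| > 0.7, P < 0.01), topology (degree, density, Louvain
   modularity with the 0.4 modular-structure flag, clustering, path
   metrics, negative:positive edge ratio), focal-class edge decomposition
   (e.g., Clostridia intra- vs inter-class), random-removal robustness
   with secondary extinctions, and efficiency-based vulnerability.

Age-biomarker discovery is included: random-forest regression on the
ordinal age code with repeated 10-fold cross-validated feature-count
selection, and an LDA effect-size (LEfSe-style) procedure with the
conventional log₁₀ score cutoff of 4.

Because the study design this emulates (hundreds of samples pooled from
many sequencing projects) is not downloadable as one artifact, the package
ships a fully seeded synthetic-data generator (`scenario_config()`,
`simulate_tree()`, `simulate_communities()`, `simulate_correlated_table()`)
that produces phylogenies, metadata and overdispersed OTU tables with
exposed ground truth: assembly regime per age group, succession of two
dominant clades, planted biomarkers and planted correlation blocks. Every
analysis stage is validated against that ground truth and against
independent oracles (picante, brute-force enumerations, closed forms).

## Worked example

```r
library(pitmudr)

# a seeded scenario: 1,000 taxa, 4 age x 4 longitude groups, 6 samples
# each, reads ~10,000/sample, early->late clade succession
cfg  <- scenario_config(seed = 1)
tree <- simulate_tree(cfg)
sim  <- simulate_communities(tree, cfg)
rel  <- to_relative(rarefy(sim$table, 10000, seed = 1))

# within-group Bray-Curtis dissimilarity declines with cellar age
gd <- group_dissimilarity(bray_curtis(rel), sim$frame)
round(as.numeric(gd$medians), 3)
#> [1] 0.770 0.609 0.466 0.321
gd$trend$slope; gd$trend$p_value
#> [1] -0.149145
#> [1] 0.0003797102
```

The four numbers are the median within-group Bray–Curtis dissimilarities
for Aa, Ab, Ac, Ad: young cellars host highly dispersed communities
(median 0.77) that converge with age (0.32), and the regression of the
medians on age rank is significantly negative — the succession signature
the pipeline is built to detect. The same objects feed the other stages,
e.g. `beta_nti(rel, tree, frame = sim$frame)` for assembly fractions and
`correlation_screen()` → `build_network()` → `topology()` for networks.

A full run with artifacts on disk (alpha/distance/βNTI/fraction tables,
GraphML networks, robustness curves, biomarker tables, a manifest with
md5 sums) is one call:

```r
run_pipeline(run_config(scenario = cfg, out_dir = "out", seed = 1))
```

or from a shell via `inst/scripts/pitmud-pipeline.R --config cfg.yaml`.

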