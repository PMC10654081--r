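---
title: "Models and methods behind pitmudr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pitmudr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pitmudr analyses spatiotemporal 16S surveys of Baijiu fermentation pit mud:
clay-lined anaerobic cellars whose microbial communities succeed over
decades to centuries of continuous use. The pipeline starts from an OTU
count table, a rooted phylogeny, taxonomy and sample metadata (cellar-age
groups Aa < Ab < Ac < Ad and longitude groups La–Ld), and asks three
questions: how diversity and composition change along the age gradient,
whether community assembly is driven by stochastic or deterministic
processes, and how co-occurrence structure and its stability evolve. This
vignette explains the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology was genuinely open.

## Diversity

Alpha diversity uses the bias-corrected Chao1 estimator
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ ($F_1$, $F_2$: singletons, doubletons),
Shannon entropy on natural logarithms, and Pielou evenness $H/\ln S_{obs}$.
The bias-corrected Chao1 is defined when no doubletons exist and collapses
to $S_{obs}$ without singletons; Pielou is undefined for single-taxon
samples and returned as `NA`. Counts are first rarefied to even depth by
seeded subsampling *without* replacement (multivariate hypergeometric), so
column sums hit the target exactly and proportions are unbiased; samples
below the depth are dropped with a warning. Temporal trends are ordinary
least-squares fits of an index (or a taxon's relative abundance) on
numeric age; when only group labels are available, the representative ages
5, 30, 100 and 350 years stand in for Aa–Ad (configurable via
`age_group_years()`).

Beta diversity offers Bray–Curtis (via vegan) and an in-package
*normalized* weighted UniFrac,
$\sum_b l_b\,|A_b - B_b| \,/\, \sum_b l_b\,(A_b + B_b)$ over branches $b$
with descendant-tip abundance fractions $A_b, B_b$ — the normalized form
keeps values in $[0,1]$. NMDS is vegan's rank-based engine with 20 seeded
random restarts and up to 500 iterations, best stress kept and coordinates
centered. PERMANOVA uses sequential (Type-I) sums of squares with term
order age before longitude, mirroring a residual that excludes both
factors; the order is an argument. Group comparisons of alpha indices use
one-way ANOVA with Tukey's HSD adjustment; within-group dissimilarity
distributions are compared by Kruskal–Wallis plus Holm-adjusted pairwise
Wilcoxon tests, and their temporal trend is a regression of group medians
on age rank. Within-group dispersion is measured on all within-group
pairwise distances (not distances to centroids) — the simplest reading of
box-plot style summaries; this is a documented, configurable choice.

## Community assembly: βMNTD and βNTI

For samples $k$ and $m$, the abundance-weighted between-community mean
nearest taxon distance is

$$\beta MNTD = 0.5\Big[\sum_{i_k} f_{i_k}\min_{j_m}\Delta_{i_k j_m}
 + \sum_{i_m} f_{i_m}\min_{j_k}\Delta_{i_m j_k}\Big],$$

with $f$ the within-sample relative abundances over taxa present in the
sample and $\Delta$ cophenetic distances; taxa shared by both samples are
their own nearest neighbours at distance zero. The null model shuffles
taxon identities across the tips of the phylogeny (999 shuffles by
default), preserving every sample's abundance vector and richness, and

$$\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}})\, /\,
  \mathrm{sd}(\beta MNTD_{null}).$$

βNTI $> 2$ is read as heterogeneous selection, $< -2$ as homogeneous
selection, and $|\beta NTI| \le 2$ as stochastic assembly (the boundary
value is classified stochastic; the selection rules are strict
inequalities). Per-group process fractions are computed over within-group
pairs only; cross-group pairs are computable but excluded by default.
Pairs whose null distribution is degenerate (sd = 0, possible for
near-empty samples) are flagged and excluded from fractions with a
warning. A within-sample variant (`ses_mntd()`) exposes the standard
nearest-taxon index through the same null machinery. The kernel is
compiled (Rcpp): one tip permutation serves all pairs, and each sample's
nearest-taxon distance field is computed once per permutation, making 999
shuffles over a hundred samples a matter of seconds.

## Co-occurrence networks

Edges are Spearman rank correlations (average-rank ties, asymptotic
t-test) passing $|\rho| > 0.7$ and $P < 0.01$ — deliberately *without*
multiple-testing correction, the stated convention of the correlation
screen this pipeline reproduces; an FDR toggle exists but defaults off.
Before screening, taxa are filtered to prevalence ≥ 20% of the group's
samples and mean relative abundance ≥ 0.01%, which curbs rank-tie
artifacts at rarefied depth (both thresholds configurable). Networks are
built at the OTU level and annotated by class for display and for the
focal-class decomposition (intra- vs inter-class, by sign), since
published node counts imply OTU-level graphs even when figures are
colored by class.

Topology reports nodes, edges, average and weighted degree, density,
average clustering coefficient, components, the negative:positive edge
ratio, and modularity as the best of 10 seeded Louvain runs on $|\rho|$
weights; modularity > 0.4 is flagged as modular structure (strict). Path
length and diameter are computed on the largest connected component with
unweighted hops, since they are undefined on disconnected graphs.
Robustness removes a fraction of nodes uniformly at random (grid step
0.05, 100 draws per step by default), then iteratively drops nodes left
without neighbours (secondary extinction); the score is the trapezoidal
area under the mean remaining-fraction curve. On complete graphs this
reproduces the closed form $1-q$ until fewer than two nodes survive.
Vulnerability is the maximal relative drop in global efficiency (mean
inverse shortest path) caused by deleting one node; natural connectivity
is exposed as an alternative stability index.

## Biomarker discovery

`rf_select()` regresses composition on the ordinal age code 1–4 (numeric
years optional) with random forests. Within each of 10×5 cross-validation
folds, taxa are ranked by permutation importance on the training portion
and forests are refit on ranked prefixes from a Fibonacci-like grid (1, 2,
3, 5, 8, 13, …), recording held-out mean-squared error; the selected size
minimizes the mean CV error (ties to fewer taxa), and the reported taxa
are the top of a final all-sample ranking. The Fibonacci grid makes the
"least cross-validation error" search tractable without committing to an
arbitrary linear grid.

`lefse()` follows the LDA effect-size shape: per-feature Kruskal–Wallis
across groups at $\alpha = 0.05$; survivors enter 30 bootstrap rounds that
draw two-thirds of each group, fit a one-dimensional linear discriminant
over the surviving features (pooled within-class covariance shrunk by
$\lambda = 10^{-6}$ toward a scaled identity, so degenerate bootstraps
stay well-posed), and score each feature by the average of two
extreme-group mean differences: that of its discriminant component and
that of the raw feature. The raw term matters: the variance-normalized
discriminant systematically down-weights the largest (and noisiest)
effects, so without it a hundred-fold enrichment can fall below the
conventional cutoff. The score is $\log_{10}(1 + \text{mean effect})$ on abundances scaled to
parts-per-million, so the conventional threshold of 4 corresponds to an
effect of 10⁴ ppm ≈ 1% absolute abundance difference. There is no
subclass stage (the design has none). The effect-size composition of the
original method is not fully specified in print, so this definition is
fixed, documented, and validated by permutation-null tests (false
positives at the α level) and planted-enrichment recovery rather than by
bit-compatibility with any particular implementation.

## The synthetic-data generator

Every stage is testable offline against scenarios with exposed ground
truth. A scenario draws:

* a **phylogeny**: birth–death tree conditioned on the tip count
  (`ape::rphylo`), by default 1,000 tips with extinction near speciation
  (death 0.999 at birth 1). The high-turnover regime matters: it yields
  the tight clusters-plus-deep-divergences structure of real 16S trees.
  Pure-birth trees of a few hundred tips are nearly star-like, a Brownian
  trait on them is almost independent of topology, and no parameter
  setting then produces the phylogenetically clustered turnover that
  selection must leave behind — this is why the default scale is 1,000
  tips rather than a few hundred;
* a **trait** by Brownian motion on that tree, the axis on which
  selection acts;
* a **metacommunity**: log-normal pool abundances (`meta_sdlog`, default 1);
* per-sample **environmental optima**: one shared value per group under
  homogeneous selection, independent per-sample values under heterogeneous
  selection, ignored under neutral drift. Optima are anchored at the trait
  of a randomly drawn tip so the fitness window sits on a realized trait
  clump rather than between clades. Taxon fitness is
  $\exp(-s'(t_i - E)^2)$ with $s'$ the selection strength normalized by
  twice the trait variance; strength 0 makes all three regimes emit
  byte-identical draws;
* **ecological drift** as a per-sample colonization lottery: each taxon
  arrives with probability `presence` (default 0.35) and colonizers get
  log-normal abundance noise (`sd` 0.5). Without presence turnover,
  replicate communities share essentially all abundance mass, and shared
  taxa sit at distance zero in both the observed and the null βMNTD — no
  assembly signal of any kind can exist. Drift dispersion declines along
  the age gradient (factors 1, 0.75, 0.5, 0.25), so young communities are
  the most dispersed, which is also what produces the decreasing
  within-group Bray–Curtis trend;
* **succession**: the weights of two disjoint tree clades are crossed
  over by complementary logistic factors of log10 age (replacement rate 3,
  dominance boost 15), replacing the early dominant clade by the late one
  across Aa→Ad;
* optional **planted biomarkers** (per-group fold-changes) and
  **correlation blocks** (latent Gaussian copula with within-block
  correlation, rank-preserving log-normal transform) for the biomarker
  and network stages;
* **counts**: Dirichlet-multinomial at the configured depth, with
  precision `depth - 2` giving roughly twice multinomial variance, the
  overdispersion scale typical of amplicon replicates.

Everything is a deterministic function of one integer seed.

The canonical assembly-recovery scenarios (used by the test suite) run
the default scale with succession disabled, a flat metacommunity
(`meta_sdlog = 0`), colonization probability 0.6, drift noise 0.3 with
uniform age factors, and selection strength 30. These values were
calibrated once against the generator so that each regime expresses its
signature clearly — strong shared-optimum selection drives within-group
βNTI below −2, divergent optima drive it above +2, and neutral scenarios
stay within the stochastic band — and then frozen.

What the generator does *not* emulate: compositional coupling beyond the
copula fixture, chimeras and primer artifacts (upstream of the pipeline),
spatial autocorrelation within longitude groups, and the taxonomic
identity of real pit-mud lineages (labels are synthetic). Passing the
recovery tests therefore shows the estimators respond correctly to the
modelled mechanisms, not that any particular real dataset will show the
same effect sizes.

## Numerical choices and degenerate inputs

* Rarefaction requires integer counts and errors when every sample falls
  below the depth; a depth equal to the sample total is an exhaustive,
  exact draw.
* Aggregation pools taxa unassigned at a rank into an explicit
  `unassigned` row so per-sample totals are conserved to 1e-9.
* Distances: identical samples give exactly 0; weighted UniFrac refuses
  taxa absent from the tree (prune first with `match_tree()`, which
  reports what it drops).
* βNTI: a degenerate null (sd = 0) flags the pair rather than producing
  ±Inf; classification rejects NaN.
* Correlation screen: constant taxa have undefined rank correlation and
  are skipped with a warning; `|rho| = 1` pairs get p = 0 rather than a
  negative-variance t statistic.
* Louvain is stochastic, so modularity is the maximum over 10 runs with
  consecutive seeds; robustness and the forest/LEfSe bootstraps consume
  one seeded stream each, making all pipeline outputs byte-identical
  under a fixed configuration and seed.
* Problem sizes in the test suite are chosen so each property runs well
  inside its stated allowance: the null self-consistency check uses 50
  disjoint sample pairs on a 100-tip tree; regime recovery runs three
  full default-scale scenarios; the forest recovery fixture plants 12
  monotone OTUs among 120 at 64 samples.

## Known limitations

* βNTI's detectable effect size grows with tree size and per-sample
  richness; at a few hundred tips even strong simulated selection cannot
  push most pairs past $|z| = 2$. Interpret small-scale studies
  accordingly.
* The LEfSe effect size is a fixed, documented variant, not a clone of
  the original implementation.
* PERMANOVA, NMDS and Bray–Curtis are delegated to vegan and inherit its
  conventions (free permutations, monoMDS stress scale).
* The robustness metric reports the remaining-node fraction under random
  removal with secondary extinctions; published robustness curves on
  other scales (e.g., natural connectivity) are exposed separately and
  not interchangeable.
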