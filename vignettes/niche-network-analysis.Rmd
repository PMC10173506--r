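---
title: "Niche breadth and co-occurrence network methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche breadth and co-occurrence network methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichewebs)
```

This vignette documents the statistical methods the package implements,
the choices made where conventions diverge, and what the synthetic-data
generator does and does not emulate.

## The analysis pipeline

The pipeline takes an ASV-by-sample count table, per-sample environmental
covariates, and optional taxonomy, and proceeds:

1. **Low-count removal.** ASVs with a summed count below 4 (singletons,
   doubletons, tripletons) are removed; these are the taxa most likely to
   be sequencing artifacts. The threshold is configurable
   (`filter_low_count()`).
2. **Niche breadth and classification.** Levins' breadth
   `B = 1/Σ P²` is computed per ASV, by default from per-sample relative
   abundances (removing sequencing-depth artifacts) re-normalized within
   the ASV so that `Σ_i P_ij = 1` and `B ∈ [1, N]`. ASVs with mean
   relative abundance below 2×10⁻⁵ or prevalence below 25 samples are
   excluded before classification — extremely rare taxa would
   masquerade as specialists. Cutoffs: fixed (`B > 78` generalist,
   `B < 22` specialist; sensible on a 225-sample design) or data-driven
   (`suggest_thresholds()`: Tukey fence `Q3 + 1.5·IQR` above which B
   values are distributional outliers, and the lower quartile).
3. **Co-occurrence networks.** For each niche category and for all
   categories together, ASVs passing the network filter (prevalence ≥ 25
   and relative abundance > 0.05 % in at least one sample) are stacked
   with the numeric covariates and all-pairs Spearman correlations are
   computed from midranks over pairwise-complete observations. Two-sided
   p-values use the t approximation `t = ρ√((n−2)/(1−ρ²))`; one
   Benjamini–Hochberg correction is applied over every tested pair in the
   network under construction (ASV–ASV, ASV–environment, and
   environment–environment together — a single family is the conservative
   choice when no partition is specified). Edges require `ρ > 0.5`,
   `p < 0.001`, and `q < 0.001`, all strict, positive correlations only.
   Environment–environment edges are retained but flagged and excluded
   from topology statistics; isolated nodes are dropped.
4. **Topology and null models.** Whole-network statistics follow the
   NetworkAnalyzer conventions: density `2m/(n(n−1))`; mean local
   clustering with degree-<2 nodes contributing 0; path length and
   diameter over connected pairs (the networks are disconnected; a
   largest-component variant is available); degree heterogeneity
   `√var(k)/mean(k)` with population variance; centralization
   `(n/(n−2))(max k/(n−1) − density)`. The null model is G(n, m) —
   uniform over graphs with exactly the observed node and edge counts —
   with per-metric means over 100 replicates (means and standard errors
   are both reported; the replicate count is configurable). The
   small-world coefficient is `SW = (C/C_R)/(L/L_R)`.
5. **Modules and node roles.** Louvain community detection (igraph) runs
   under a fixed seed for reproducibility; the achieved partition's
   modularity is recomputed independently from the Newman definition
   `Q = Σ_s (e_s/m − (d_s/2m)²)`. Per node, the within-module degree
   z-score Zi (population standard deviation, with Zi = 0 when a module
   has zero spread or one member) and the participation coefficient
   `Pi = 1 − Σ_s (k_is/k_i)²` classify nodes at the conventional
   thresholds Zi = 2.5 and Pi = 0.62 into peripherals, connectors,
   module hubs, and network hubs. Environment nodes are excluded from
   role statistics by default — roles describe microbes.
6. **Module patterns.** Major modules (size ≥ max(5, 2 % of nodes); the
   rule is a tunable default since observed module-size spectra differ
   between datasets, and the output reports the resulting coverage) are
   summarized by feature-scaling each member ASV's relative-abundance
   profile to [0, 1] and averaging per sample. Patterns are clustered
   with Ward's method on Euclidean distances (`hclust` `ward.D2`, the
   squared-Euclidean Ward criterion; `ward.D` available), correlated with
   covariates by Spearman, and inter-module connectivity is tabulated as
   `e_s/(n_s(n_s−1)/2)` within and `e_st/(n_s n_t)` between modules,
   displayed as percentages rounded half away from zero to one decimal.
   The environment subnetwork is the induced subgraph on environment
   nodes and their direct ASV neighbors (ASV–ASV edges excluded by
   default, flag to include), with per-factor niche-category composition.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_total` | 4 | reads | removes singleton–tripleton ASVs |
| `min_mean_rel_abund` | 2e-5 | proportion | rare taxa mimic specialists |
| `min_prevalence` | 25 | samples | ~10 % of a 225-sample design |
| `upper`, `lower` | 78, 22 | B units | generalist / specialist cutoffs |
| `rho_min`, `alpha` | 0.5, 0.001 | — | strict edge thresholds |
| `null_reps` | 100 | graphs | null-mean precision vs. runtime |
| `z_threshold`, `p_threshold` | 2.5, 0.62 | — | role taxonomy |
| `major_min_fraction`, `major_min_size` | 0.02, 5 | — | major-module rule |

Boundary conventions: the abundance and prevalence filters are inclusive
(`≥`), edge thresholds strict (`>`, `<`), and the niche cutoffs leave
both boundary values to the common class. Quantiles use linear
interpolation (R type 7) throughout.

## The synthetic community generator

`scenario_config()` encodes the study design the pipeline targets:

* **Design.** 225 samples in three elevation strata (75 each; stratum
  elevations 162 ± 43, 251 ± 21, 302 ± 39 m).
* **Covariates.** ~15 environmental variables linear in standardized
  elevation plus Gaussian noise, with field-realistic directions:
  moisture and vascular plant cover high at low elevation; soil
  temperature, cryptogam cover, rock cover, and dry/wet weight ratio
  high at high elevation; pH flat at 5.1 ± 0.3. Percentage covers are
  clamped to [0, 100].
* **Causal cascade.** A latent vegetation variable is indicated by
  vascular plant (dominant) and cryptogam cover. Generalist log-abundance
  responds to vegetation; common taxa respond to the mean generalist
  signal; specialists respond to the mean common signal. This is the
  top–down chain environment → vegetation → generalists → common taxa →
  specialists.
* **Niche structure.** Gaussian niche responses along elevation: width
  600 m for generalists (flat across the ~250 m gradient, hence
  near-uniform occupancy and high B), 35 m for common taxa, 8 m for
  specialists (occupancy concentrated in one stratum, hence low B).
* **Planted modules.** Four correlation blocks live in the common and
  specialist taxa: members share a block elevation optimum (habitat
  patch) and a latent log-scale factor (loadings 2.2 / 2.4). Factors are
  zero-sum across blocks within each sample, so blocks trade off along
  the gradient and the community total stays stable. Generalists carry
  no planted block: their co-occurrence arises from the shared
  vegetation response, so they form their own vegetation-driven module
  in the inferred network — mirroring the flat, single-cluster behavior
  of generalist modules on real gradients. Because of this, block
  recovery (adjusted Rand index against Louvain modules) is evaluated on
  the taxa that carry a planted block.
* **Background taxa and counts.** 80 module-free common taxa (moderate
  niches, independent optima) carry the community mass that real
  datasets hold outside any co-occurrence module, and 20 near-zero ASVs
  (1–3 reads) exercise the low-count filter. Counts are negative
  binomial (size 10) around expected proportions scaled to a log-normal
  sequencing depth with mean ~34,000 reads per sample (the scale of a
  typical MiSeq run over 225 soil samples).

Effect sizes are desk-scale choices made for recoverability of the
planted structure, not estimates of any real community; they were fixed
once during design. What passing recovery tests demonstrate is that the
pipeline's estimators are consistent with their own generative
assumptions — not that real tundra data meet those assumptions. Features
of real data the generator does **not** emulate: spatial autocorrelation
beyond the elevation axis, phylogenetic signal in niches, compositional
artifacts of PCR/primer bias, and the heavy tail of thousands of rare
ASVs.

## Numerical choices

* **Determinism.** Every stochastic step (generator, rarefaction, null
  models, Louvain, layouts) takes a seed and restores the caller's RNG
  state; identical configs give byte-identical TSV outputs.
* **Degenerate inputs.** All-zero abundance vectors are errors for B and
  Shannon; all-zero samples are flagged and left zero by
  `relative_abundance()`; constant vectors feature-scale to zeros with a
  warning; zero-variance variables yield undefined correlations that are
  excluded downstream; pairs with fewer than 10 complete observations
  are not tested; modules with no spread give Zi = 0.
* **Rarefaction** subsamples without replacement (`vegan::rrarefy`);
  samples below the target depth are dropped, not upsampled, because
  subsampling without replacement is undefined there.
* **Closeness** follows the `(reachable count)/(distance sum)` component
  convention (harmonic variant available); betweenness is unnormalized
  by default.
* **Louvain** runs under a fixed seed; its modularity is cross-checked
  against an independent implementation of the Newman formula at 1e-12.

## Problem sizes

The shipped defaults — 225 samples, ~310 ASVs (40 generalists, 125
common, 45 specialists, 80 background, 20 rare), 4 planted blocks, 100
null replicates — give a full pipeline run in tens of seconds and keep
the complete test suite and the acceptance script to a few minutes on
one CPU, while preserving every structural feature the analysis relies
on (three strata, a realistic covariate suite, compositional counts,
planted blocks, and a generalist/specialist contrast with the observed
B-value geometry).

## Known limitations

* Spearman co-occurrence on relative abundances is not
  compositionally-aware; spurious correlation from the simplex
  constraint is mitigated only by the strict thresholds
  (compositionality-aware methods are out of scope).
* The published "average number of neighbours" of network-analysis
  tools does not always equal `2m/n` for printed node/edge counts
  (plugin-specific accounting); this package reports `2m/n`.
* The major-module rule is a size heuristic; the printed major-module
  counts of any given study depend on their (unstated) criterion, so
  coverage is always reported alongside the flags.
* Negative co-occurrences are filtered out by design (`positive_only`),
  matching the convention of the niche-breadth network literature;
  mutual-exclusion structure is invisible to this analysis.
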