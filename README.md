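# nichewebs

Niche-breadth classification of microbial habitat generalists and
specialists, plus co-occurrence network analysis with Erdős–Rényi null
normalization — an R re-implementation of the analysis pipeline used to
study how vegetation structures soil bacterial communities along Arctic
elevation gradients.

## Who this is for

Microbial ecologists with an ASV-by-sample count table (16S amplicon or
similar), per-ASV taxonomy, and per-sample environmental covariates, who
want to:

1. classify taxa into **habitat generalists, common taxa, and
   specialists** from Levins' niche breadth;
2. build **Spearman co-occurrence networks** (per niche category and in
   total, optionally including environmental covariates as nodes) with
   Benjamini–Hochberg FDR edge filtering;
3. normalize network topology against **G(n, m) Erdős–Rényi null models**
   and compute the small-world coefficient;
4. assign **Guimerà–Amaral node roles** (peripheral / connector /
   module hub / network hub) from the within-module degree Zi and
   among-module connectivity Pi;
5. summarize **module distribution patterns** along the environmental
   gradient (feature scaling, Ward dendrograms, module–environment
   correlations, inter-module edge accounting, environment subnetworks).

A synthetic elevation-gradient community generator with full ground truth
(`simulate_community()`) makes every stage testable without sequencing
data.

## The statistics at the core

**Levins' niche breadth** for taxon *j* over *N* samples:

    B_j = 1 / Σ_i P_ij²

where `P_ij` is the share of taxon *j*'s abundance found in sample *i*
(`Σ_i P_ij = 1`). `B = 1` for a taxon confined to one sample and `B = N`
for a perfectly even taxon. Taxa with `B` above an upper cutoff are
generalists, below a lower cutoff specialists, and common otherwise; the
classical cutoffs on a 225-sample design are `B > 78` and `B < 22`, and
`suggest_thresholds()` derives data-driven cutoffs (Tukey fence
`Q3 + 1.5·IQR` for generalists, lower quartile for specialists).

**Co-occurrence edges** are positive Spearman correlations with
`ρ > 0.5` and both the t-approximated p-value and the BH-adjusted
q-value `< 0.001`.

**Small-world coefficient** against an Erdős–Rényi null with the same
node and edge counts:

    SW = (C / C_R) / (L / L_R)

with C the mean local clustering coefficient, L the characteristic path
length over connected pairs, and `C_R`, `L_R` their null-model means.

**Node roles** use `Zi` (z-score of a node's within-module link count,
population sd) and `Pi = 1 − Σ_s (k_is / k_i)²`, with thresholds
`Zi = 2.5` and `Pi = 0.62`.

## Worked example

```r
library(nichewebs)

sim      <- simulate_community(scenario_config(), seed = 1)
counts   <- filter_low_count(sim$table)            # drop totals < 4
profiles <- niche_profiles(counts, thresholds = "data")
attr(profiles, "thresholds")
#>     upper     lower
#> 117.65301  21.90626

category_summary(profiles, counts)
#> # A tibble: 4 × 4
#>   category   n_asvs mean_share sd_share
#>   <chr>       <int>      <dbl>    <dbl>
#> 1 generalist     40   0.352     0.185
#> 2 common        177   0.568     0.175
#> 3 specialist     72   0.0799    0.0723
#> 4 excluded        1   0.000226  0.00142

net <- build_conetwork(counts, metadata = sim$metadata, profiles = profiles)
net
#> <conetwork> 304 nodes (289 ASV, 15 environment), 8754 edges (rho > 0.5, p & q < 0.001)

topology_summary(conetwork_graph(net), reps = 100, seed = 2)
#>   n_nodes n_edges modularity clustering path_length c_ratio l_ratio small_world
#> 1     304    8708      0.641       0.81        2.56    4.29    1.41        3.03
```

Reading: of the 290 ASVs surviving the low-count filter, 40 are
classified generalists (they hold 35 ± 19 % of each sample's reads), 177
common, 72 specialists, and one is excluded by the abundance/prevalence
filters. The co-occurrence network keeps 8,708 ASV/environment edges
after dropping the flagged environment-environment ones; its clustering
is 4.3× and its path length 1.4× the Erdős–Rényi expectation, giving a
small-world coefficient of 3.0 — the network is strongly clustered yet
short-pathed, as tundra soil networks are.

`run_pipeline(pipeline_config())` chains all stages (four networks:
generalist, common, specialist, total; topology; Louvain modules; node
roles; module patterns and environment correlations) and returns a
manifest of per-stage counts; `report()` prints a compact summary, and
`autoplot()`, `plot_niche_breadth()`, `plot_zipi()`,
`plot_module_patterns()` draw the standard figures.

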