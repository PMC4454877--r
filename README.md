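# streamnet

Beta diversity and co-occurrence network analysis for 16S amplicon OTU
tables, built for studies of temporary (intermittent) headwater streams and
similar systems where the question is how microbial community structure and
the web of taxon associations respond to environmental state — here, flow
status (permanent, temporary-flowing, temporary-dry), habitat (sediment,
water, soil), site, and season.

The package is aimed at microbial ecologists who have a rarefiable OTU count
table plus sample metadata and want a reproducible, seeded pipeline from raw
counts to publishable statistics: ordination, group tests, shared-taxon
partitions, richness, and a null-model-validated co-occurrence network with
keystone-taxon candidates.

## What it computes

**Preprocessing.** Rarefaction to a common depth by subsampling without
replacement (default 8960 sequences per sample), and removal of OTUs below
0.1% of total sequences (both configurable, in either order).

**Beta diversity.** Bray-Curtis dissimilarity
`d(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`; principal coordinate analysis via
eigendecomposition of the Gower-centered matrix `−½ J D² J`, with per-axis
variance fractions `λ_i / Σ λ⁺`; ANOSIM with
`R = (r̄_between − r̄_within) / (N(N−1)/4)` on midranked distances and a
seeded permutation p-value, plus pairwise group comparisons and an exact
enumeration mode for tiny designs. Shared-OTU (Venn) partitions over any
metadata grouping, and Chao1 richness
`S_chao1 = S_obs + F1²/(2F2)` (bias-corrected when `F2 = 0`) with its
classical standard error.

**Co-occurrence network.** Pairwise Spearman `ρ` between OTUs (midrank
Pearson; two-sided p from the t approximation); an undirected edge wherever
`ρ > 0.75` and `p < 0.05` (strict; both thresholds configurable). Networks
are validated against 1000 Erdős–Rényi `G(n, m)` random graphs with matching
node and edge counts: mean clustering coefficient `C`, mean path length `L`,
and Newman modularity `Q` (greedy agglomerative partition) are compared with
the null ensemble, and each empirical p is the proportion of null values
strictly greater than the observed one. Nodes carry the flow status of the
sample where the OTU peaks, its maximum abundance, and its taxonomy lineage;
keystone candidates are ranked per cluster by closeness centrality
(1 / mean geodesic distance), with degree and geodesic betweenness reported
alongside.

**Synthetic data.** A generator with known ground truth — lognormal
baselines, per-site/habitat/date multipliers, and planted co-occurrence
blocks built by a Gaussian copula over negative-binomial marginals so that a
block attains a chosen pairwise Spearman correlation. Every downstream stage
has a recovery test against this ground truth.

## Worked example

The shipped demo emulates a three-site, three-date design (two permanent
sites, one temporary site that runs dry in August; sediment and water
sampled each date) with one co-occurrence block tied to permanent conditions
and one to dry conditions:

```r
library(streamnet)
demo <- make_demo("streamnet_demo", seed = 1)
res  <- run_pipeline(demo$config)

res$ordination
#> PCoA: 17 samples, 2 axes
#> variance explained: 60.3%, 13.6%

res$anosim$global[c("R", "p")]     # groups: flow class x habitat
#> $R  0.5459293
#> $p  0.002

res$null_model
#> Erdos-Renyi G(n, m) null model (1000 draws)
#>   clustering   observed 0.7727, null mean 0.2865, p = 0
#>   path_length  observed 1.0147, null mean 1.8232, p = 1
#>   modularity   observed 0.5355, null mean 0.2197, p = 0

head(res$keystone[, c("otu_id", "cluster", "rank", "degree", "closeness")], 3)
#>     otu_id cluster rank degree closeness
#> 1 OTU_0001       1    1      8         1
#> 2 OTU_0031       1    2      8         1
#> 3 OTU_0032       1    3      8         1
```

Reading the output: one April water sample falls below the rarefaction
depth and is dropped (17 of 18 samples analyzed). ANOSIM finds clear group
structure (`R = 0.55`, `p = 0.002` over 999 permutations). The network's
clustering and modularity exceed every one of 1000 size-matched random
graphs (`p = 0`), so its two tight clusters — which recover the planted
blocks — are not a chance feature; its mean path length is *smaller* than
random because the statistic averages over connected pairs and the network
is two dense, separate modules. The keystone table ranks each cluster's
most central OTUs.

All outputs (preprocessed table, distance matrix, ordination, ANOSIM JSON,
Venn JSON, Chao1 table, edge list, GraphML, null-model JSON, keystone table,
heatmap matrix, run manifest) land in `streamnet_demo/results/`. Rerunning
with the same seed reproduces every file byte for byte.

A thin command-line wrapper is installed with the package:

```sh
streamnet demo --seed 1
streamnet run --config cfg.yaml
streamnet network --table t.tsv --metadata m.tsv --rho-min 0.75 --alpha 0.05
```

(Invoke via `Rscript $(Rscript -e 'cat(system.file("exec/streamnet", package="streamnet"))')`
or add that path to `PATH`.)

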