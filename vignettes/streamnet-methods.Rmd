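---
title: "Methods: beta diversity and co-occurrence networks for stream OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta diversity and co-occurrence networks for stream OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and data model

`streamnet` analyzes OTU count tables (rows = OTUs, columns = samples,
nonnegative integers) with per-sample metadata: site, habitat (sediment,
water, soil), flow status (permanent, temporary_flowing, temporary_dry) and
collection date. The canonical on-disk format is the classic tab-separated
OTU-table dialect (`#OTU ID` header cell, optional trailing `taxonomy`
column of pipe- or semicolon-delimited lineages); BIOM-JSON is read through
`biomformat` when available. Sequence-level processing (read merging, OTU
picking, chimera removal, taxonomy assignment) is out of scope — the package
starts from the count table.

# Preprocessing

**Rarefaction** equalizes sampling effort by drawing, for each sample,
exactly `depth` sequences without replacement from that sample's sequence
multiset (a multivariate hypergeometric draw). Samples whose total falls
below `depth` are dropped with a warning; an all-short table is an error.
Each sample draws from an RNG substream keyed by its sample id, so the
result is independent of column order and of which other samples are
present. The default depth of 8960 matches the workflow the package
reimplements; for synthetic data any depth below the simulated sequencing
depth (default ~20,000) behaves equivalently.

**Low-abundance filtering** removes OTUs holding strictly less than
`min_fraction` (default 0.001, i.e. 0.1%) of the pooled sequence total;
an OTU exactly at the threshold is retained. The pooled-total reading
follows the phrase "of total sequences"; a per-sample variant (retain an
OTU reaching the fraction in at least one sample) is available but off by
default. The filter is idempotent at a fixed fraction.

**Order.** Whether the abundance filter ran before or after rarefaction is
not documented in the source workflow; the pipeline defaults to rarefy →
filter (the filter then sees depth-equalized counts) but accepts either
order, and the run manifest records which was used.

# Beta diversity

**Bray-Curtis.** `d(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`; 0 for identical,
1 for disjoint communities. All-zero samples are rejected by name (the
dissimilarity is undefined for them).

**PCoA.** Metric multidimensional scaling: eigendecomposition of
`B = −½ J D² J` with `J = I − 11ᵀ/n`. Coordinates are eigenvectors scaled
by `√λ`; the variance fraction of axis *i* is `λ_i / Σ λ⁺` over positive
eigenvalues only. Bray-Curtis is a semi-metric, so negative eigenvalues are
expected; they are reported but excluded from the variance decomposition,
and no Lingoes/Cailliez correction is applied by default — matching the
common default of ecological ordination software. Eigenvalues within
`1e-9 · max(1, |λ|max)` of zero are treated as null; an all-zero distance
matrix yields all-zero coordinates with a warning, and requesting more axes
than positive eigenvalues truncates with a warning.

**ANOSIM.** All `N(N−1)/2` distances are ranked with midranks on ties, and

`R = (mean between-group rank − mean within-group rank) / (N(N−1)/4)`,

so `R ∈ [−1, 1]`, positive when between-group dissimilarity exceeds
within-group dissimilarity. The permutation p-value uses the
`(1 + #{R_perm ≥ R_obs}) / (1 + n_perm)` convention (labels permuted
uniformly, seeded, default `n_perm = 999`), so `p > 0` always. A `≥`
comparison uses a `1e-12` slack so exact ties in the rank statistic are not
lost to floating-point noise.

With `exact = TRUE` every distinct label arrangement is enumerated and
`p = #{R ≥ R_obs} / n_arrangements`, observed arrangement included — the
standard exact permutation test. A consequence worth spelling out: `R` is
invariant to swapping group names, so in a 2+2 design with complete
separation the maximal `R` is attained by two of the six balanced
relabelings (the observed one and its complement) and the exact p is 2/6 =
1/3, the smallest value that design can produce. Claims of smaller exact
p-values in such designs would require treating the complement relabeling
as different from the observed one, which the statistic does not support.

**Shared-OTU partitions.** An OTU is present in a group when its summed
count over the group's samples is positive; counts are reported for every
exclusive subset of groups (Venn cells) and sum to the number of OTUs
present anywhere. In the pipeline the partition is computed on the rarefied
(pre-filter) table, since presence/absence is the quantity of interest and
the abundance filter would delete exactly the rare OTUs that drive it.

**Richness.** Chao1 with the classical variance:
`S_obs + F1²/(2F2)` when doubletons exist, else the bias-corrected
`S_obs + F1(F1−1)/(2(F2+1))`; with no singletons the estimate collapses to
`S_obs` (se 0). Chao1 deliberately stands in for parametric mixture
estimators here; outputs are labeled `chao1`.

# Co-occurrence network

**Correlation.** Spearman `ρ` is the Pearson correlation of midranks,
computed for every OTU pair; the two-sided p-value uses
`t = ρ √((n−2)/(1−ρ²))` with `n−2` degrees of freedom (the convention of
`cor.test(..., exact = FALSE)`). `ρ = ±1` maps to `p = 0`. An OTU constant
across samples has no defined rank correlation; it is recorded as `ρ = 0`,
`p = 1` with a warning rather than propagating `NA` into thresholding.
Fewer than 4 samples is an error — the t approximation is meaningless
below that.

**Edges.** A pair becomes an undirected edge iff `ρ > rho_min` (default
0.75) **and** `p < alpha` (default 0.05), both strict. Only positive
associations are kept by default — the network models co-occurrence, not
mutual exclusion — and a `signed = TRUE` flag admits `ρ < −rho_min` pairs
for exploratory use. No multiple-testing correction is applied by default,
matching the reimplemented procedure; `p_adjust = "BH"` is available and
logged when used. OTUs with no qualifying edge are excluded from the node
set, so the node count equals the number of connected OTUs.

**Node labels.** Each node carries the flow status of the sample where its
count is maximal, that maximal count, and its lineage. Ties are broken by
earliest date, then sample id, with a warning — a deterministic rule that
keeps reruns byte-identical.

**Graph statistics.** `C` is the mean local clustering coefficient with
degree-<2 nodes contributing 0; `L` is the mean geodesic length over
reachable pairs (disconnected pairs excluded; `NaN` with a warning on an
edgeless graph); `Q` is Newman modularity of a supplied partition or, when
none is given, of a greedy agglomerative modularity-maximizing partition.
Because `L` averages over connected pairs only, a fragmented network of
tight modules can have *smaller* `L` than a connected random graph — the
direction of the null-model comparison for `L` depends on topology and
should be read alongside `C` and `Q`.

**Null model.** The observed network is compared with `n_random` (default
1000) Erdős–Rényi `G(n, m)` graphs — uniform over simple graphs with the
observed node and edge counts. "Size" is read as node count *and* edge
count, the only reading that pins down a unique ensemble. Each statistic's
empirical p is the proportion of null values strictly greater than observed
(ties count as not greater; one-sided by construction), so `p = 0` means
the observed value exceeded every draw. Null modularity uses the same
greedy partitioner as the observed network; the partition algorithm behind
the original analysis is not documented, and modularity p-values are
partitioner-dependent — a caveat for quantitative comparison.

**Centrality.** Degree is the incident edge count. Betweenness credits a
node with the fraction of geodesics between unordered node pairs passing
through it (fractional credit across multiple geodesics, endpoints
excluded — the Brandes convention implemented by `igraph`). Closeness is
defined here as the inverse of the **mean** geodesic distance to reachable
nodes — the verbal definition of the source — which differs from the
classical `1/Σd` by a factor of (reachable count); nodes in singleton
components get closeness 0. Keystone candidates are the `top_k` nodes per
cluster by closeness, ties broken by higher degree then OTU id.

# Synthetic data generator

The generator plants known structure so every stage has a recovery test:

* **Baselines**: per-OTU lognormal abundances (`meanlog 0`, `sdlog 1`),
  with planted-block OTUs offset by `+0.5` on the log scale so they sit in
  the abundant tail where rank correlations survive discreteness.
* **Group structure**: per site × habitat multipliers, lognormal with
  `group_effect_sd` (default 0.4); temporal designs add per-date lognormal
  effects (`date_effect_sd`, default 0.3). Multipliers are drawn per
  *response unit*: each background OTU is its own unit, while a planted
  block shares one unit — a co-occurring module responds coherently to the
  environment, and independent member responses would dilute exactly the
  rank correlation the recovery tests control. Setting `group_effect_sd = 0`
  yields exchangeable samples (the ANOSIM null).
* **Flow-status response**: a block associated with a flow status is
  multiplied by `status_multiplier` (default 5) in samples where that
  status is active — dry-associated modules wax in dry samples.
* **Counts**: a Gaussian copula over negative-binomial marginals. Block
  members share a per-sample latent factor with pairwise latent correlation
  `r = 2 sin(π ρ_target / 6)`, the classical inversion of the
  Spearman-correlation formula for bivariate normals, and counts are
  `qnbinom(Φ(z), size, mu)`. The quantile transform is monotone, so the
  planted rank correlation is invariant to the abundance scale. Targets
  above 0.99 are rejected as infeasible for discrete counts.
* **Closure compensation**: an abundant block's shared factor also moves
  the per-sample total, and any depth normalization (relative abundance,
  rarefaction) removes that shared movement, attenuating the realized
  correlation by roughly `(1−s)²` on the latent scale for a block holding
  biomass share `s`. The generator inflates the latent correlation
  analytically by that factor, computed from the block's expected share, so
  the realized within-block Spearman correlation lands near the target
  *after* rarefaction. The calibration tolerance (realized median within
  `[0.8, 0.97]` for a target of 0.9 at 50 samples) was fixed by simulation
  before the test suite was frozen.
* **Dispersion**: `nb_size = 3`. Overdispersion is the signal carrier in
  the copula — the quantile spread is what transmits the latent factor —
  so heavier dispersion makes planted correlations *more* robust to
  rarefaction thinning, and 3 is typical of the strong overdispersion of
  real amplicon counts.
* **Determinism**: all randomness flows from one master seed through named
  substreams (baselines, multipliers, date effects, latent factors, noise,
  depths, taxonomy), so regenerating one component never perturbs another
  and tables are bitwise reproducible.

What the generator does **not** emulate: compositional mutual exclusion
(negative associations), taxonomy-dependent abundance structure, read-level
artifacts (chimeras, contamination), spatial autocorrelation within sites,
or realistic rare-tail richness (the OTU count is tens, not thousands).
Passing recovery tests therefore demonstrate that the pipeline's statistics
recover the structure they claim to measure under controlled conditions —
not that real temporary-stream data satisfy those conditions.

# Reproducibility and the pipeline

`run_pipeline()` derives a named RNG substream per stage from the master
seed (rarefaction, ANOSIM permutations, the null model), so changing
`n_random` cannot perturb ANOSIM, and a rerun with the same configuration
reproduces every TSV/JSON output byte for byte. The run manifest records
package and R versions, all parameters, the stage order, and per-stage
timings; a failing stage aborts with its name after persisting the manifest
and any completed outputs.

# Problem sizes used by the test suite

The suite verifies hand-computed values exactly (tolerance `1e-10`–`1e-12`),
checks oracle equivalence on random tables up to 12 × 12 and graphs up to
12 nodes, calibrates the `G(n, m)` sampler on 20,000 draws of `G(3, 2)` and
the null p-values on 200 repetitions at `n_random = 200`, and runs the
planted-structure recovery at the study conditions (50 samples, two blocks
of 8 OTUs at target ρ = 0.9, 24 background OTUs) over 50 seeds with 199
ANOSIM permutations, plus 200 no-effect datasets for the type-I error rate.
These sizes were chosen so the full suite completes in about a minute on a
single core while keeping every Monte-Carlo bound comfortably away from its
threshold.

# Known limitations

* Spearman-threshold networks inherit compositional artifacts: strong
  closure effects can induce (mostly negative) spurious associations that
  the positive-edge threshold suppresses but does not eliminate.
  Compositional methods (SparCC, SPIEC-EASI) are out of scope.
* Edge p-values are uncorrected across the ~`n(n−1)/2` tests by default,
  by design fidelity; at `ρ > 0.75` with ≥ 20 samples the correlation
  threshold, not the p-value, is binding.
* The exact enumeration mode of ANOSIM is limited to designs with at most
  `1e5` label arrangements.
* Closeness uses the inverse-mean-geodesic convention; compare with other
  software only after converting conventions.
* The modularity null-model p depends on the partitioner; only the greedy
  agglomerative algorithm is wired in.
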