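---
title: "Species-habitat networks: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-habitat networks: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shnet)
```

## The problem

Protected areas are often mosaics of small patches of different habitat
types, and mobile insects such as butterflies use resources across many of
them. Ranking patches by species counts alone ignores how patches interact
in supporting a shared species pool. shnet treats a survey of this kind as
a *species-habitat network*: a bipartite graph whose two node sets are
habitat patches and species, with a link of weight $w_{is}$ wherever
species $s$ was observed at patch $i$ with $w_{is}$ individuals. All
analyses start from one object, an abundance matrix of integer counts
(sites on rows, species on columns) with a habitat label per site, pooled
over sampling rounds.

The network-level metrics describe the architecture of the whole area:
whether assemblages split into habitat-bound modules (modularity), whether
species-poor patches hold nested subsets of rich ones (nestedness), how
densely patches and species are connected (connectance), and how gracefully
the system degrades as species are lost (robustness). The patch-level
metrics — centrality on the one-mode projection, community detection,
mixing — identify which individual patches carry the shared species pool
and which hold distinctive assemblages.

## Diversity indices

For each site the package computes richness $S$ (species with at least one
individual) and the Smith–Wilson evenness
$$E_{var} = 1 - \frac{2}{\pi}\arctan\!\Big(\frac{1}{S}\sum_{s}
  \big(\ln n_s - \overline{\ln n}\big)^2\Big),$$
over the $S$ observed species only ($\ln 0$ is undefined; zero counts never
enter). $E_{var}$ is 1 for perfectly even abundances, decreases with the
variance of log abundances, and is invariant to rescaling all counts. Two
conventions for the variance are in circulation; the default divides by $S$
(the population-variance form used by standard community-ecology software),
and `evar(..., variant = "sample")` divides by $S-1$. A site with a single
species returns 1 by the zero-variance convention. Both choices only matter
for very species-poor sites.

## Bipartite architecture

**Connectance** is the realized link fraction,
$C = L / (n_{patches} \cdot n_{species})$.

**Weighted NODF** measures nestedness on the 0–100 scale. For a pair of
rows (and symmetrically columns) of the sorted matrix, the upper row $i$
and lower row $j$ contribute $100\,|\{k: 0 < w_{jk} < w_{ik}\}| / fill_j$
when the pair's ordering key strictly decreases, 0 otherwise; the statistic
averages over all row and column pairs. Two versions of the decrease
condition exist in the literature's implementations: on the *binary fill*
(number of occupied cells, with weighted totals breaking sort ties only)
and on the *weighted marginal totals*. They can differ appreciably — a
fully filled 2x3 matrix with strictly decreasing weights scores 100 under
totals but 75 under fill, because its full columns tie on fill. Published
quantitative NODF values are normally produced by the fill-based code path,
so `weighted_nodf()` defaults to `condition = "fill"` (verified in the test
suite to agree exactly with vegan's quantitative NODF); the strict
totals-based reading remains available as `condition = "totals"`.

**Barber modularity** scores a joint partition $g$ of patches and species:
$$Q = \frac{1}{W}\sum_{i,s}\Big(w_{is} - \frac{s_i t_s}{W}\Big)
  \delta(g_i, g_s),$$
with patch strengths $s_i$, species strengths $t_s$ and total weight $W$.
`optimize_modularity()` searches for the maximizing partition with
alternating greedy label propagation between the two node sets followed by
agglomerative module merging, restarted from random initial labellings (20
restarts by default) with the best partition kept. The single-module
baseline ($Q = 0$) and any supplied starting partition (the pipeline seeds
one from the habitat labels) are always among the candidates, so the
returned $Q$ is never below either. The search is stochastic; given the
same seed it is exactly reproducible. Because no search implementation
guarantees the global optimum on a 44 x 74 network, replicated values from
different optimizers should be compared with a tolerance of a few
hundredths.

One behaviour worth knowing: with skewed weights the optimum can
legitimately subdivide a fully occupied, internally homogeneous block,
because clusters of large counts act as real modules under the weighted
null term. Planted-structure recovery is therefore assessed in the tests
with even abundances (where the component partition is provably optimal)
or through agreement and purity scores rather than raw module counts.

**Null models and z-scores.** Significance of nestedness and modularity is
calibrated against fixed-margin null matrices drawn uniformly given the
observed row and column totals (the classic contingency-table allocation
algorithm, via `stats::r2dtable()`), 1000 replicates by default. The
z-score uses the population standard deviation of the null values; a null
ensemble with zero spread is flagged degenerate instead of returning an
infinite z. Null modularity is itself optimized on every replicate; the
replicate search uses fewer restarts (4 by default) than the observed
matrix (20), since only the ensemble mean and spread matter. Note that a
z-score against fixed-margin nulls responds to *any* departure from
margin-conditioned uniformity: matrices whose occupied cells carry
heavy-tailed counts score strongly positive modularity z even with no
habitat structure at all, because the null redistributes the total far more
evenly than a log-normal abundance process. Interpreting modularity z as
habitat signal therefore requires the companion agreement statistics
(below), not the z alone.

**Robustness.** Species are removed rarest-first (increasing total
abundance; ties broken by species label so the order is deterministic, or
randomly under `tie_seed` for sensitivity checks). A patch is lost when its
last species is removed. The extinction curve runs from (0, 1) to (1, 0)
and $R$ is its area by the trapezoidal rule including both endpoints —
the removal direction is the only part fixed by convention, so the
integration rule and the binary survival criterion (a patch survives while
at least one species remains, regardless of abundance) are documented
package choices.

## The patch projection

Two patches are linked when at least one species occurs at both; the edge
weight is the *number* of shared species (presence-based: abundances decide
occupancy, not edge weight). Per patch, degree $k$ counts linked patches
and strength $s$ sums shared-species counts. **Weighted degree centrality**
blends them as $C(\alpha) = k^{1-\alpha} s^{\alpha}$; $\alpha = 0$ is pure
degree, $\alpha = 1$ pure strength, and the conventional default
$\alpha = 0.5$ (the geometric mean) rewards patches with both many and
strong connections. Shared-species networks have integer weights $\ge 1$,
so $s \ge k$ and centrality is non-decreasing in $\alpha$. Ties in the
ranking get their average rank.

**Community detection** clusters patches by shared species with three
weighted algorithms (via igraph): multilevel/Louvain greedy modularity
optimization, walktrap (random-walk agglomeration; walk length 4, the
common default, as no value is canonical), and spinglass (simulated
annealing of a Potts model; 25 spins, $\gamma = 1$, connected graphs
only). Each returned partition carries the Newman–Girvan weighted
modularity of the partition on the patch graph.

**Mixing parameter.** For a partition, each node's external fraction is
the share of its links leaving its community; the package reports both the
degree-based average $\mu_k = \langle k_{ext}/k \rangle$ and the
strength-based $\mu_s = \langle s_{ext}/s \rangle$ (isolated nodes are
excluded). No single definition of $\mu$ is standard, which is why both
are always reported side by side. The degree-based form saturates on dense
graphs — once every patch pair shares at least one species the graph is
complete and $\mu_k$ is pinned at the between-community edge fraction —
while the strength-based form keeps responding to how *many* species cross
community lines; trend analyses should prefer $\mu_s$.

**Partition agreement** uses the adjusted Rand index (permutation-model
chance correction; 1 for identical partitions, expectation 0 for
independent ones) to quantify how well detected communities match the
a-priori habitat map.

## Habitat-effect models

Richness, evenness and centrality are each regressed on habitat type by
ordinary least squares with treatment coding, so the intercept is the
reference habitat's mean and each coefficient a difference of means, with
two-sided t-tests. The reference level defaults to the habitat with most
sites and should be pinned explicitly when comparing against published
tables. All-pairs comparisons use Tukey's HSD on the studentized range
(classical pooled-variance form, which handles unbalanced groups through
the standard error of each pairwise difference), summarized as a compact
letter display by insert–absorb: habitats sharing no letter differ at the
stated level. Pearson correlations between centrality and the diversity
indices carry the usual two-sided t-test.

## The synthetic landscape generator

`generate_landscape()` emulates the shape of a heterogeneous protected-area
survey so the entire pipeline is testable without field data. The default
design is five habitat types with 10, 10, 10, 7 and 7 patches (44 sites)
and 74 species, split into 8 specialists per habitat plus 34 generalists —
the sites-per-habitat layout mirrors a realistic unbalanced sampling
design, and the specialist/generalist split reflects the common finding
that a large fraction of a butterfly fauna uses multiple habitats.
Specialists occupy own-habitat sites with probability `p_in = 0.6`, other
sites with `p_out = 0.1`; generalists occupy any site with
`p_gen = 0.35`. These defaults give an expected connectance near 0.28,
typical of such surveys. Occupied cells draw abundances as
$\lceil \text{lognormal}(\mu_{ln} = 1, \sigma_{ln} = 1.2) \rceil$, giving
strictly positive integer counts with realistic skew (site maxima an order
of magnitude above the mean). Sites or species left empty by the occupancy
draw are redrawn (and recorded in the planted-truth object) so the result
always satisfies the container invariants. `generate_nested()` plants
nestedness instead: species ranges shrink geometrically
($\lceil n e^{-\text{decay}\, s}\rceil$ capacity-ranked sites) with weights
decreasing down the ranking.

What the generator does *not* emulate: spatial autocorrelation of patches,
temporal (per-round) structure, detection error, and the abundance
covariance structure of real communities. Passing recovery tests on
synthetic landscapes therefore shows the machinery measures what it claims
to measure on data with known truth — not that real landscapes behave like
the generator.

## Numerical and design notes

* **Determinism.** Every stochastic stage takes a seed; the pipeline fans a
  single seed out to per-stage seeds with fixed offsets, so adding a stage
  never perturbs another stage's stream, and identical configuration plus
  seed yields byte-identical report bundles.
* **Degenerate inputs.** All-zero sites or species violate the container
  invariants and are rejected (or dropped under an explicit flag with a
  warning); binary 0/1 matrices trigger a warning because weighted metrics
  degenerate on presence/absence data; single-row or single-column
  matrices are refused by the nestedness metric and trivially determined
  under fixed margins.
* **Tie-breaks.** Extinction order ties break lexicographically by species
  label (or randomly under a seed); tied centralities share average ranks;
  tied marginal keys in weighted NODF contribute zero.
* **Problem sizes in the test-suite simulations.** Recovery sweeps run on
  3-habitat, 12-site, 18-species landscapes with 20 replicates per grid
  point and 20-replicate null ensembles; these sizes give stable trend
  estimates for the properties under test while keeping the suite quick to
  run.
* **Known limitations.** The analyses are not spatially explicit — patch
  adjacency, distance and autocorrelation play no role; modularity search
  is heuristic (tolerances above); the robustness curve ignores abundance
  thresholds below which a population is no longer viable.

## A worked run

```{r example, eval = FALSE}
land <- generate_landscape(seed = 1)
fit <- shn(land$matrix, n_nulls = 1000, seed = 1)
fit
summary(fit)
plot(fit, "curve")
write_report(fit, "shn-results")
```
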