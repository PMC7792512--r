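# shnet — species–habitat network analysis

Protected areas are rarely one habitat: they are mosaics of grassland
successional stages, meadows and wetlands, and mobile insects such as
butterflies use resources across many patches at once. Ranking patches by
species counts alone misses those cross-patch associations. **shnet**
analyses a survey of this kind as a *species–habitat network* — a weighted
bipartite graph linking species to the habitat patches where they occur —
and is aimed at community ecologists and conservation planners who want
both whole-area architecture metrics and per-patch rankings from a single
site × species abundance matrix with habitat labels.

From one input object the package computes:

* **Diversity**: per-site richness *S* and Smith–Wilson evenness
  *E*<sub>var</sub> = 1 − (2/π)·arctan((1/S)·Σ(ln *n*<sub>s</sub> −
  mean ln *n*)²).
* **Bipartite architecture**: connectance; weighted NODF nestedness
  (0–100); Barber bipartite modularity
  *Q* = (1/W)·Σ(*w*<sub>is</sub> − *s*<sub>i</sub>*t*<sub>s</sub>/W)·δ(*g*<sub>i</sub>, *g*<sub>s</sub>)
  maximized by a seeded label-propagation + agglomeration search;
  robustness *R* (area under the rarest-first extinction curve); z-scores
  of nestedness and modularity against fixed-margin (Patefield) null
  matrices.
* **Patch projection**: a one-mode patch graph weighted by shared species;
  Opsahl weighted degree centrality
  *C*(α) = *k*<sup>1−α</sup>·*s*<sup>α</sup> with ranking; community
  detection (multilevel, walktrap, spinglass); mixing parameter µ; adjusted
  Rand agreement with the habitat map.
* **Habitat effects**: OLS models of richness/evenness/centrality on
  habitat type with treatment coding, Tukey HSD compact letter displays,
  and Pearson correlations.
* **Synthetic landscapes**: a generator with planted habitat structure
  (specialists vs. generalists, log-normal abundances) and a planted-truth
  record, plus a nested-matrix generator, so the whole pipeline can be
  exercised and validated without field data.

## Worked example

```r
library(shnet)

land <- generate_landscape(seed = 1)   # 44 sites x 74 species, 5 habitats
fit <- shn(land$matrix, n_nulls = 1000, seed = 1)
fit
```

```
Species-habitat network analysis
  44 patches x 74 species, 5704 individuals
  connectance = 0.28, weighted NODF = 14.08 (z = -65.0)
  modularity = 0.41 (z = 132.5, 10 modules), robustness = 0.98
  communities: multilevel = 5, walktrap = 5, spinglass = 4
  centrality (alpha = 0.50): mean 106.67 (min = 87.56, max = 121.80)
```

Reading the output: about 28% of all possible patch–species links are
realized; the network is far less nested (negative weighted-NODF z) and far
more modular (positive modularity z) than fixed-margin chance; robustness
near 1 means patches survive long into a rarest-first species removal.
Community detection groups the 44 patches into 4–5 clusters that align
with the planted habitat types (adjusted Rand index 0.67 for multilevel),
and high-centrality patches are those sharing many species with the rest
of the landscape. Per-response habitat models are in `fit$models`:

```r
fit$models$fits$richness
```

```
Habitat effect on richness (reference: habitat1)
                 term estimate   se     t       p
 Intercept (habitat1)    21.20 1.08 19.59 8.8e-22
             habitat2     0.40 1.53  0.26 8.0e-01
             habitat3    -1.20 1.53 -0.78 4.4e-01
             habitat4    -0.91 1.69 -0.54 5.9e-01
             habitat5    -1.49 1.69 -0.88 3.8e-01
```

The intercept is the reference habitat's mean richness and each coefficient
a difference of means against it (here the generator plants no richness
differences, and none are detected). `summary(fit)` adds mixing, agreement
and correlation summaries; `plot(fit, "curve")` draws the extinction
curve; `write_report(fit, dir)` exports the full plain-text bundle
(metrics JSON with the effective configuration, per-site tables,
memberships, curve, coefficient tables).

Real data enter through `read_abundance("matrix.csv")` — CSV with a site
column, a habitat column and one integer count column per species. A thin
command-line wrapper over the same functions is installed at
`inst/scripts/shn-cli.R` (`analyze` and `simulate` subcommands).

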