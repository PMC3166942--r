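---
title: "Collapsing grouped rows: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsing grouped rows: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowcollapse)
```

## The problem

High-dimensional genomic analyses repeatedly face the same aggregation step:
several rows of a numeric matrix measure one underlying entity, and a single
row per entity is needed. Three canonical instances drive this package:

* **probes to genes** — microarray platforms carry several probes per gene;
  merging studies run on different platforms requires one measurement per
  gene identifier;
* **genes to modules** — a co-expression module (a cluster of genes) is
  summarized by a single centroid profile;
* **markers to cell types** — the expression of a cell type's marker genes in
  a mixed-tissue sample is summarized into one relative-abundance profile
  per type ("expression deconvolution").

All three reduce to the same operation: given a matrix (rows = variables,
columns = samples) and a row-to-group map, produce one row per group. The
package implements that operation (`collapse_rows()`), the network machinery
behind its hub-based variant, a cross-dataset reproducibility framework for
choosing among collapsing strategies, the marker-based deconvolution
pipeline, hypergeometric gene-list enrichment for interpreting the resulting
groups, and seeded simulators that generate data with the structure each
analysis assumes.

## Collapsing methods

Methods fall into two families.

**Representative methods** select one existing row per group; the output row
is a bit-identical copy of the selected input row. Selection is by row score:
mean over non-missing entries (`MaxMean`, `MinMean`), mean absolute value
(`absMaxMean`, `absMinMean`), or unbiased sample variance
(`maxRowVariance`). A row with fewer than two non-missing values has no
defined variance and loses all comparisons under `maxRowVariance`.

**Composite methods** compute a new row per group: the column-wise mean over
non-missing entries (`average`), the first principal component of the group
(`ME`, the *module eigengene*), or an arbitrary user function
(`method = "function"`).

Before either family runs, each group is by default trimmed to the rows with
the fewest missing values (`select_fewest_missing = TRUE`). Ties in the row
score go to the row with the highest mean; any remaining ties are broken
uniformly at random under a recorded seed, so pipelines are reproducible.

### Connectivity-based collapsing

The network variant builds, within each group, a *signed weighted
correlation network*: for rows $x_i$ and $x_j$ the adjacency is

$$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^{\beta},$$

with Pearson correlation on pairwise-complete samples. The signed form keeps
the direction of association: $r = -1$ maps to adjacency 0, $r = +1$ to 1,
and $r = 0$ to $2^{-\beta}$. The soft-thresholding power $\beta$ defaults to
1 because groups are typically small (a handful of probes per gene), where
further down-weighting of moderate correlations costs information. A node's
connectivity is $k_i = \sum_{j \ne i} a_{ij}$, and connectivity-based
collapsing selects the row with the highest $k$ — the group's *hub*, the row
most positively correlated with the rest of the group.

Correlation networks on one or two rows are not meaningful, so the dispatch
rule is: groups of three or more (trimmed) rows use the hub; two-row groups
fall back to the configured representative method; singletons pass through.
If several rows tie for the maximum connectivity, the first such row in
input order is chosen.

Six named strategies bundle these options (`strategy_config()`): `1.max`,
`2.var`, `3.kMax`, `4.kVar`, `5.ME`, `6.Avg`; the evaluation and
deconvolution layers refer to strategies by these names, and `"none"`
denotes the uncollapsed baseline in the evaluation framework.

### Numerical choices

* **Missing values.** `average` uses per-column means over non-missing
  entries; `ME` imputes each missing cell with its row mean (logged) before
  standardization. Pairwise correlations require at least 3 shared
  non-missing samples, the minimum for a non-degenerate Pearson coefficient;
  rarer overlap is an error rather than a silent `NA`.
* **ME scaling and sign.** The eigengene is the first right-singular vector
  of the row-standardized group submatrix: unit Euclidean norm, oriented so
  that its correlation with the group's mean profile is non-negative (a
  first PC has arbitrary sign, and the downstream uses are
  correlation-based, so a deterministic orientation is required). If every
  row is constant the eigengene is undefined; the package warns and returns
  zeros. Zero-variance rows within a mixed group carry no direction and are
  standardized to zero rows.
* **Variance.** `maxRowVariance` uses the unbiased ($n-1$) estimator. After
  missing-value trimming, rows within a group share the same missing count,
  but counts can differ across groups, so the estimator choice is fixed and
  documented rather than left to chance.
* **Ties.** Score ties are exact floating-point ties. The documented
  tie-breaks (highest mean, then seeded random; first row for connectivity)
  are the only places where input row order or the seed can influence the
  result; everything else is permutation invariant.
* **Ordering.** Output rows are written in sorted group order, never file
  order, for determinism across runs and inputs.
* **Trimming vs dispatch.** When trimming leaves exactly two rows in a group
  under connectivity-based collapsing, the fallback representative method
  applies — the trim runs first, then dispatch examines the trimmed size.

## The reproducibility framework

Which strategy to use is an empirical question. The framework compares
strategies by how reproducible their output is across independent datasets:
for each unordered pair of datasets and each strategy, both datasets are
collapsed, restricted to shared groups, and compared by

* the Spearman correlation of per-row mean expression (ranked means), and
* the Spearman correlation of whole-network connectivity, where a signed
  network is built per dataset over all shared rows after collapsing, with
  the same $\beta$.

`compare_strategies()` aggregates over pairs into means, standard errors
(sample SD / $\sqrt{\text{pairs}}$), and win fractions — the share of pairs
in which a strategy attains the pair's highest correlation, with exact ties
splitting the win equally so the total is conserved. Spearman uses average
ranks for ties. Connectivity is computed over all shared rows blockwise, so
memory stays bounded for networks of thousands of rows.

## Marker-based deconvolution

`select_markers()` ranks genes per cell type by fold-change enrichment in
that type's pure profiles: $(\bar{x}_{\text{type}} + \varepsilon) /
(\bar{x}_{\text{other}} + \varepsilon)$ with pooled non-target columns in
the denominator and pseudocount $\varepsilon = 1$ guarding zeros on the
linear intensity scale (log-scale input can be unlogged via `log_base`). A
gene enriched in several types is assigned to its best type only, keeping
panels disjoint — collapsing requires one group per row. Only genes with
fold change above 1 qualify; a short panel is truncated with a warning.

`predict_proportions()` collapses the panel's marker rows in the mixture
matrix per cell type under any strategy, then divides each type's collapsed
row by its sum across samples, so every type sums to 1 across samples. The
estimate is proportional to, not equal to, the true proportion — like
relating two temperature scales — so accuracy is scored by Pearson
correlation with the truth (`score_predictions()`, pooled and per type),
which is scale invariant. The truth matrix is renormalized by the same
convention before correlating. Eigengene-based predictions can be negative;
they are scaled by their signed sums and flagged. `marker_count_sweep()`
repeats the pipeline over a grid of panel sizes to expose each strategy's
robustness to the number of markers.

## Enrichment

`enrich_lists()` tests every (user list, reference list) pair for overlap
with the upper-tail hypergeometric probability $P(X \ge k)$, Bonferroni
corrected across all pairs. The background universe is a required, logged
argument: an enrichment p-value is meaningless without an explicit
background, and no default can be safely inferred from the lists alone.
Symbols are upper-cased and trimmed before matching, and genes outside the
universe are dropped with logged counts.

## What the simulators emulate — and what they do not

The generators produce data with exactly the structure the analyses assume,
plus planted truth for validation. All randomness is Gaussian, all
generators are bit-reproducible from their seed, and none attempts
platform-specific artifacts (probe-set chemistry, batch effects, intensity
saturation). Passing tests on these fixtures therefore demonstrate that the
algorithms recover the structure they target when that structure is present
— not that any particular strategy is best on a given real dataset.

**Probe–gene pairs** (`simulate_probe_gene_pair()`): each gene has a
baseline level and a factor loading shared between two datasets; each probe
measures `baseline + signal_fraction × latent + noise`. The planted carrier
probe has the largest signal fraction and a baseline bump, so the
highest-mean probe is also the best-correlated one. Defaults: 100 genes,
1–4 probes per gene, 20 samples per dataset, carrier fraction 0.9 versus
0.2–0.6, noise SD 0.5 — per-probe reliabilities typical of array data. Under
a unit-variance latent, two probes with signal fractions $a_1, a_2$
correlate in expectation at $a_1 a_2 / \sqrt{(a_1^2 + \sigma^2)(a_2^2 +
\sigma^2)}$, which the tests verify by Monte Carlo.

**Modules** (`simulate_modules()`): members are `loading × eigengene +
noise`. The defaults define a clear-hub, low-noise regime: hub loading 0.95
against member loadings uniform on (0.2, 0.5), noise SD 0.15, modules of 10
rows, 40 samples. The separation matters: loadings translate into
correlations through $l / \sqrt{l^2 + \sigma^2}$, which saturates as $l$
grows, and the hub's connectivity margin must exceed the sampling noise of
correlation estimates (roughly $(1 - r^2)/\sqrt{n}$ per pair). With member
loadings up to 0.75 at 30 samples that margin collapses and hub recovery is
no better than ~75%; the chosen defaults keep recovery near certainty, so
failures of hub selection indicate algorithmic errors rather than an
ill-posed instance.

**Mixtures** (`simulate_mixture()`): pure profiles carry planted markers —
"on" level uniform on (5, 15) in the marker's own type, "on"/fold elsewhere,
with per-marker specificity fold log-uniform on (5, 20) — plus 200
non-specific background genes; mixtures are proportion-weighted combinations
of the pure profiles under per-sample Dirichlet(2) proportions (columns sum
to 1), observed under multiplicative noise with CV `noise_sd` (default 0.10,
a moderate array-like error; 0 gives noise-free data) and an optional floor
at zero emulating intensities (the clamp slightly biases fold changes at
high noise). Because proportions sum to 1 within each sample, every marker's
noise-free mixture profile is an *affine* function of its own type's
proportions; representative and average collapses of affine profiles remain
affine, so noise-free deconvolution achieves per-type correlation exactly 1
without requiring perfectly specific (infinite-fold) markers. Under noise,
the multiplicative error model links a marker's noise amplitude to its total
level: low-specificity markers have high baselines (high mean, poor
signal-to-noise), which is precisely the regime where picking the
highest-mean marker is fragile and picking the best-connected marker is
robust.

## Problem sizes in the test suite

The shipped tests validate against brute-force oracles on 200 random
matrices (groups of up to 8 rows, 8–12 samples, 10% missingness), recover
planted hubs over 200 simulated module replicates, score deconvolution over
50 noisy mixture replicates, evaluate null and identity dataset pairs over
100 replicates, and check hypergeometric p-values exhaustively over all
universes up to size 20. These sizes give Monte-Carlo error comfortably
below the asserted margins while keeping the suite quick to run.

## Known limitations

* Group assignments are taken as given; the package neither detects modules
  nor re-annotates probes, and wrong annotations propagate silently.
* Only Pearson-based signed soft-threshold networks and the connectivity
  centrality are implemented; other association measures (mutual
  information) and centralities are out of scope.
* Deconvolution estimates relative abundance up to a per-type constant; it
  cannot produce absolute per-sample composition, and `6.Avg` is an
  unweighted average (a weighted composite can be supplied through
  `method = "function"`).
* Binary microarray formats, normalization and background correction are
  out of scope; inputs are assumed preprocessed, delimited text.

## A worked example

```{r example}
sim <- simulate_probe_gene_pair(n_genes = 40, n_samples = c(15, 15), seed = 1)
res <- collapse_rows(sim$data[[1]], sim$groups, method = "MaxMean")
res

# how often the highest-mean probe is the planted signal carrier
mean(res$group2row[sim$planted$gene] == sim$planted$carrier_probe)

ds <- list(list(mat = sim$data[[1]], groups = sim$groups),
           list(mat = sim$data[[2]], groups = sim$groups))
compare_strategies(ds, strategies = c("1.max", "2.var", "3.kMax"))
```
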