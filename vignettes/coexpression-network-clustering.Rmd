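---
title: "Coexpression network clustering: model, parameters and validation design"
author: "coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression network clustering: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

## The model

`coexnet` treats a multi-tissue expression atlas as a weighted
undirected graph over features (probe sets or genes). After replicate
averaging, each feature is a profile of natural-scale intensities
across condition columns. Two features are connected when the Pearson
correlation of their profiles reaches the edge cutoff; the edge weight
is the correlation itself. The working assumptions are those of every
correlation-network analysis:

* intensities are already normalized and on a common natural scale, so
  the arithmetic mean over replicates is meaningful;
* co-membership in a transcriptional program manifests as high
  *linear* profile correlation across a sufficiently diverse set of
  conditions;
* correlation strength carries information beyond the threshold, which
  is why edge weights (not a binarized adjacency) drive the random
  walk below.

Clusters are found with the Markov Cluster algorithm (MCL): the
column-stochastic transition matrix of the graph is alternately
*expanded* (matrix self-multiplication, letting the random walk flow)
and *inflated* (elementwise powering plus column renormalization,
sharpening strong flow), until the flow matrix converges. Attractor
rows — nodes retaining positive self-flow — define the clusters as the
supports of their rows.

## Parameters, defaults, and why

All tunables live in one `coexp_config()` object.

| parameter | default | units / meaning |
|---|---|---|
| `intensity_threshold` | 100 | natural-scale intensity a feature must reach in ≥ 1 condition; below it, microarray signal is indistinguishable from background |
| `corr_cutoff` | 0.9 | minimum Pearson r for an edge (inclusive); high enough that chance correlations are rare, low enough to keep programs connected |
| `inflation` | 2.2 | MCL granularity; the standard choice for highly structured expression graphs — higher values fragment programs, lower ones merge tissues |
| `expansion_power` | 2 | random-walk steps per iteration |
| `min_cluster_size` | 5 | smallest reported cluster; below this, "cluster" membership carries little guilt-by-association evidence |
| `fold_threshold` | 5 | fold change of cluster mean expression for a tissue-specificity call (inclusive at exactly fivefold) |
| `alpha` | 0.05 | Bonferroni-corrected significance for enrichment |
| `prune_threshold` | 1e-5 | MCL entries below this are zeroed each iteration (then columns renormalized), keeping the flow matrix effectively sparse |
| `convergence_tol` | 1e-8 | stop when the largest elementwise change over one iteration falls below this |
| `max_iterations` | 200 | hard cap; exceeding it raises an error carrying the per-iteration deltas |

## Numerical and procedural choices

Several details of the procedure are under-determined by the
high-level description; the package fixes them as follows.

**Filter timing.** The low-intensity filter speaks of low *average*
expression, so by default it is applied to the averaged condition
columns (averaging first, then filtering). The alternative —
filtering raw replicate columns first — is exposed as
`filter_before_averaging = TRUE` for sensitivity analysis.

**Self-loops.** Before normalization every node receives a self-loop
equal to its maximum incident edge weight, the standard damping of the
random walk's periodicity on weighted graphs; isolated nodes get a
unit loop. This keeps a node's self-affinity on the same scale as its
strongest neighbour, whatever the local correlation level.

**Attractor interpretation.** After convergence, rows with positive
diagonal flow are attractors; each attractor row's support is a
system, and systems sharing an attractor node are merged. A
non-attractor node can in principle still sit in several merged
systems; such overlap is resolved deterministically — the larger
system wins, ties go to the system whose lexicographically smallest
member sorts first. The same seed-free tie-break orders equal-sized
clusters for naming, so `ClusterNNN` identifiers are reproducible
across runs and platforms.

**Per-component processing.** Expansion and inflation act columnwise
and preserve block-diagonal structure, so MCL is run independently on
each connected component; the result is provably identical to running
on the whole graph, and peak memory is bounded by the largest
component rather than the full node set. Pearson correlation is
likewise computed in row chunks so that no intermediate beyond the
result matrix is materialized.

**Degenerate inputs.** Zero-variance features have no defined
correlation; they are excluded from the graph with a warning and
recorded on the correlation matrix (`attr(-, "excluded")`). An empty
post-filter matrix warns rather than fails. Fewer than three condition
columns is an error (a correlation over two points is meaningless).
A missing or non-numeric expression cell is a parse error — intensity
tables are dense, and silent imputation would corrupt correlations.

**Specificity reference.** "Fivefold of the other tissues" compares a
condition's cluster mean against the *mean* of the remaining condition
means by default; `specificity_reference = "max"` gives the stricter
variant against their maximum. The comparison is inclusive at exactly
the threshold, and a zero reference with positive expression counts as
a call. Note the mean-reference rule is monotone in the threshold:
raising `fold_threshold` never adds calls.

**Bonferroni family.** The correction multiplies each cluster's raw p
values by the number of terms tested *for that cluster* (terms with at
least one cluster member). The family could equally be defined as all
terms across all clusters; per-cluster families are the less
aggressive, more common convention for per-cluster reports, and the
choice is visible in the output (`p_bonferroni / p_raw` = terms
tested).

**Score rounding.** Weighted annotation scores are reported both exact
and rounded to two decimals half-away-from-zero (`round_half_away()`),
matching how such tables are conventionally printed; base `round()`
half-to-even would differ on boundary cases.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emulates the *structure* of a curated microarray
atlas: non-negative natural-scale intensities, replicate samples
grouped into condition columns, modules of genes sharing a
tissue-restricted profile, and a majority of genes with no planted
structure. The default design — 6 modules × 30 genes, 8 conditions ×
3 replicates, on-intensity 1000 versus off-intensity 100, 10%
multiplicative lognormal noise, 200 background genes — is the fixed
validation condition used throughout the tests and the acceptance
script.

Background genes are given a per-gene lognormal baseline
(meanlog log 300, sdlog 0.5 across genes) multiplied by the same
condition-level noise `sigma` as the rest of the design. The baseline
spread models the realistic fact that different genes sit at different
expression levels, and — because Pearson correlation is invariant to
per-gene affine scaling — it contributes nothing to any correlation.
The only correlation-relevant dispersion is `sigma`, which keeps
background profiles light-tailed so their pairwise correlations
concentrate near zero. One residue is irreducible: with only 8
condition columns the null distribution of r has
P(r ≥ 0.9) ≈ 1.2 × 10⁻³ per pair, so a handful of chance edges per
dataset — including occasional attachments of a background gene to a
module — are expected and observed. Recovery is therefore scored by
adjusted Rand index (truth labels = module ids plus one `background`
class; recovered labels = cluster ids plus one `unclustered` class,
the convention familiar from module-simulation studies where
"unassigned" is a colour like any other) rather than by demanding a
perfect partition.

What the generator does **not** emulate: probe-level artifacts,
normalization residue, batch effects, correlated background programs
(housekeeping covariation), heavy-tailed expression distributions, or
one-to-many probe–gene structure. Passing the synthetic validation
therefore shows the pipeline machinery is correct under clean planted
structure; it does not certify behaviour under real-data pathologies,
where the filter, the cutoff and the inflation value interact with
normalization quality.

`perturb_module()` scrambles one module's condition profiles
(independently per gene, replicates moving with their condition),
destroying within-module correlation while preserving each gene's
intensity distribution — a minimal model of a perturbed expression
program whose genes then scatter over the remaining clusters, raising
dispersal entropy. `generate_replication_pair()` produces two datasets
sharing module structure for a configurable fraction of genes with a
configurable id-map dropout, the skeleton of a cross-dataset
replication analysis where concordance denominators must count only
mappable genes.

## Concordance conventions

Cross-dataset comparisons collapse one-to-many id mappings to the
lexicographically first target (deterministically, with a message),
use mappable genes only in denominators, and keep an explicit
`unclustered` bin so that each source cluster's fractions sum to one
exactly. Dispersal entropy is the natural-log Shannon entropy of that
distribution: 0 for an intact cluster, ln 2 for an even two-way split.

## Validation problem sizes

The test suite validates: edge sets against a brute-force O(n²) loop
(up to 200 features); MCL partitions against an independently written
dense reference implementation (graphs up to 50 nodes); hypergeometric
p values against exhaustive enumeration of all draws (backgrounds up
to 12 genes, all feasible K, n, k); module recovery, perturbation
dispersal and replication concordance on the default synthetic design
over 20 seeds each. These sizes were chosen so the full suite runs in
well under a minute while covering every code path at scales where the
independent oracles are exact.

## Known limitations

* Dense per-component MCL: components beyond ~10⁴ nodes are outside
  the intended scale; no sparse/out-of-core path is provided.
* Pearson-only association: no Spearman or mutual-information
  alternative, by design.
* GO namespaces are treated as presence/absence flags; no term
  ancestry propagation, so "annotated" means "has at least one term",
  however uninformative.
* The enrichment test is over-representation only (one-sided).
* Graph layout and visualization are out of scope; `plot()` methods
  summarize sizes and mean profiles only.
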