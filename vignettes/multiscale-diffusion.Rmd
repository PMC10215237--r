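---
title: "Multiscale diffusion profiles for network pharmacology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale diffusion profiles for network pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmnet)
```

## The problem

Herbal medicines and other multi-compound interventions act through many
weak interactions rather than one strong one. Two complementary
computational readouts support a therapeutic hypothesis for such an
intervention against a disease:

* **target overlap** — the intervention's protein targets coincide with
  disease-associated proteins more often than size-matched random target
  sets would; and
* **network propagation** — even targets that do not coincide with
  disease proteins may sit close to them in the interactome, so the
  *propagated* effect of the compound resembles the propagated effect of
  the disease.

`pharmnet` implements both, on a *multiscale* network that joins three
layers: physical protein–protein interactions, protein-to-biological-
function annotations, and a hierarchy among biological functions.
Including function nodes lets a compound and a disease "meet" at the
level of a shared biological process even when their protein
neighborhoods are disjoint.

## Diffusion profiles

Every entity (a compound, anchored on its target proteins; a disease,
anchored on its protein set) is summarized by the stationary
distribution of a random walk with restart:

$$ r = (1 - c)\, s + c\, W^\top r $$

* `s` — the restart vector, uniform over the entity's anchor nodes.
* `c` — the continue probability; with probability `1 - c` the walker
  teleports back to `s`. Default **0.85**, the standard setting for
  personalized network propagation; small `c` keeps the profile near the
  anchors, large `c` mixes toward global network structure.
* `W` — the row-stochastic transition matrix. Out-edge probabilities are
  proportional to per-edge-class scalar weights
  (`pp`, `pf`, `fp`, `ff_up`, `ff_down`), so the walk can be biased
  toward or away from the function layer. Default weights are **all 1**
  (an unbiased walk): the optimized weights used by full-scale multiscale
  interactome studies are dataset-specific and not transferable to
  arbitrary networks, so the neutral default is the only defensible
  generic choice. All five weights are user-configurable.

The profile is a probability vector over *all* nodes (proteins and
functions), in fixed lexicographic node order.

### Numerical choices

* **Power iteration** starts at `r₀ = s` and stops when the L1 change
  drops below `tolerance` (default **1e-6**; `maxIterations` 1000). The
  update is a contraction with modulus `c`, so the error decays
  geometrically and the iteration count is about
  `log(tol) / log(c)` (≈ 85 at the defaults).
* **Dangling nodes** (no out-edges, possible with one-way hierarchy
  edges) teleport their mass to the restart vector each step — the
  standard personalized-ranking convention that preserves stochasticity.
* **Convergence is reported, never assumed**: a profile that hits the
  iteration cap carries `converged = FALSE` and a warning.
* Two independent oracles guard the implementation: a direct sparse
  solve of `(I − c W'^\top) r = (1 − c) s` (with dangling rows replaced
  by `s`), and an explicit simulated walker whose empirical visit
  frequencies are compared through batch-means standard errors. Batch
  means matter because consecutive walker positions are autocorrelated;
  naive binomial standard errors would be too small.

### Ranking and its assumptions

Compounds are ranked by Pearson correlation between their full profile
and the disease profile. Correlation is computed over the complete node
vector, not a top-k truncation: truncation makes the score depend on an
arbitrary cutoff and discards exactly the low-frequency structure in
which compound and disease profiles differ most. A perfectly uniform
profile has no defined correlation and is reported as an error rather
than silently coerced.

The disease restart vector anchors on disease *proteins* only, not on
function nodes: disease protein sets come from protein-level evidence,
and anchoring on functions would double-count the annotation layer the
walk already traverses.

## Overlap statistics

* `hypergeomOverlapTest` computes the exact upper tail
  `P(X ≥ k)` via the hypergeometric distribution — no normal
  approximation at any size. The accompanying z-score uses the
  hypergeometric null moments `μ = nK/N`,
  `σ² = n(K/N)(1−K/N)(N−n)/(N−1)`, and the combined score is
  `−ln(p)·z`, positive for enriched sets. (Web enrichment services
  compute a rank-based z against a precomputed background that cannot be
  reproduced locally; the hypergeometric z is the self-contained
  analogue, and the sign convention makes enrichment positive.)
* `monteCarloFoldEnrichment` draws size-matched random target sets from
  the background. Fold enrichment is `observed / mean(random)`; the
  empirical p uses the add-one correction `(1 + #{≥ obs}) / (n + 1)` so
  it can never be exactly zero. The null mean converges to `nK/N`, which
  the tests verify.
* **Background choice matters and is explicit.** The default background
  for drug–disease overlap is the union of target proteins in the loaded
  compound–target table (the assembled-dataset universe the random draws
  come from); the full multiscale-network protein set is selectable.
  P-values are only comparable under a common, stated background.
* Multiplicity: Benjamini–Hochberg by default, Bonferroni selectable.
  Published enrichment tables are inconsistent about which correction
  produced them, so the correction used is always recorded in the output
  header.

## Key-target filtering

`filterKeyTargets` keeps targets hit by at least `minIngredients`
distinct compounds (default 2). Compounds that lose all their targets
are dropped from the roster — a compound with no retained interaction
cannot participate in any downstream statistic — and the drop is logged.
The operation is idempotent, monotone in the threshold, and never
fabricates records; the tests verify all three against brute-force
recounts.

## Mechanism subgraphs

For a compound–disease pair, the top-k nodes (default **k = 20**,
capturing the bulk of visit-frequency mass) of each profile plus the
anchor nodes induce a subnetwork. Nodes on the compound side with no
path to any disease-side node are excluded, and vice versa; "side"
includes both anchors and top-k profile nodes. Connectivity is evaluated
ignoring edge direction — reciprocal storage makes direction immaterial
for interaction and annotation edges, and hierarchy edges should not
block a mechanism path. Because removing one node can disconnect
another, pruning runs to a fixed point; with undirected connectivity
that fixed point is exactly: keep the connected components containing at
least one node of each side, which is how it is implemented (one
component pass, provably equivalent). An empty result is a legitimate
finding — *no mechanism link* — and is returned as an empty subgraph
with a warning, not an error.

Whether top-k applies per profile or to the union is a genuine
ambiguity; per-profile is used, so the subgraph holds at most
`2k + |anchors|` nodes.

## The synthetic generator

`generateScenarioBundle` produces the study condition the tests run on.
Design choices, in the order they bind:

* **PPI topology** is preferential attachment (`igraph::sample_pa`):
  interactomes are heavy-tailed, and hubs stress a diffusion method far
  more than Erdős–Rényi graphs — a decoy compound that happens to target
  hubs is the hard negative this generator is meant to produce.
* **Function hierarchy** is a random DAG: a spanning tree over a random
  order plus extra parent links, about 2.3 parents per function,
  matching the composition of real multiscale interactomes; annotation
  edges average 2 per protein. At a 1/100 scale request the realized
  layer ratios stay within 10% of a real interactome's composition
  (verified in the tests).
* **The disease is a localized module**: a random seed protein plus a
  thinned BFS ball, 20 proteins by default — 10% of the miniature
  proteome. Localization is the property that makes diffusion
  correlation informative at all; full-scale disease sets (tens of
  proteins in a ~17,000-protein interactome, well under 1%) are *more*
  localized than this default, so the miniature is conservative.
* **Planted compounds** draw all (or a configured fraction of) their
  targets from the disease module and its direct interactors; decoys
  draw from outside that pool where possible. Target-set sizes are
  uniform on 7–64, the range typical of curated herbal-ingredient
  target sets; 14 compounds with one planted active is the default
  condition.
* **Determinism**: every stage derives its own stream from the single
  scenario seed and restores the caller's RNG state, so identical
  scenarios give byte-identical fixtures and no global random state
  leaks.

What the generator does **not** emulate: literature/annotation bias
(real target sets are enriched for well-studied proteins), correlated
target sets between chemically similar compounds, edge confidence
scores, and disease sets assembled from noisy text mining. Passing the
planted-recovery tests therefore shows the *method* recovers a
network-proximity signal when one exists; it does not certify
performance on any real dataset.

## Problem sizes used by the tests

The test suite and acceptance script run on miniatures sized so the
direct-solve oracle stays exact and fast: networks of 75–800 nodes
(20 of them for the oracle-equivalence sweep), a 10⁶-step walker run,
exhaustive hypergeometric enumeration to N = 12, 200 null-calibration
runs, and 20 independently seeded studies for planted-compound recovery.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite completes in well under a
minute of compute per property.

## Known limitations

* Identifier matching is exact string equality; cross-vocabulary mapping
  (gene symbol vs. Entrez vs. UniProt) must happen before loading.
* Edge-class weights are taken as given, never optimized; weight
  learning requires held-out indications and is out of scope.
* The pipeline evaluates one disease per run.
* Correlation of diffusion profiles is descriptive, not inferential: no
  p-value is attached to a correlation score, because profile entries
  are strongly dependent and no exchangeable null is available at this
  scale. The overlap statistics carry the inference.
* On networks whose disease module spans a large fraction of all
  proteins, diffusion correlation loses discrimination (every profile
  resembles the global stationary distribution); the overlap test
  degrades much more gracefully. This is a property of the method, and
  the reason the synthetic disease defaults to a small module.
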