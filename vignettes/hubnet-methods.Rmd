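---
title: "Hub-bottleneck gene prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-bottleneck gene prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

## The analysis model

`hubnet` implements the standard topological prioritization of disease
genes from a protein–protein interaction (PPI) network. The network is a
simple undirected graph over gene symbols: interactions carry no
direction, self-interactions are discarded, and parallel listings (the
doubled rows of STRING exports) are collapsed to one edge, keeping the
maximum confidence score. Disease-query downloads typically leave a
sizeable fraction of the gene list without any interaction; the
decomposition into connected components therefore separates a main
component — where all centrality analysis happens — from isolated nodes,
with deterministic ordering (size descending, then lexicographically
smallest member) so every downstream artifact is reproducible.

All shortest-path computations are **unweighted**: confidence scores can
filter edges at ingestion (`min_score`) but never act as distances. This
matches how PPI topology is conventionally analyzed — a score is a
belief about an edge's existence, not a transport cost.

### Centrality metrics

Four metrics are computed from first principles on the main component,
with nodes processed in sorted order so floating-point accumulation is
bit-reproducible on a platform:

* **degree** — incident edge count; defined for every node.
* **betweenness** — Brandes' single-source dependency accumulation over
  all sources, halved to count unordered pairs, normalized by
  `(n−1)(n−2)/2`. Normalization puts values in [0, 1], the range
  NetworkAnalyzer-style tools report.
* **closeness** — `(n−1) / Σ d(u, v)`, in (0, 1] on a connected
  component.
* **stress** — the same Brandes sweep with *unit* (not fractional)
  accumulation: for source `s`, the count of geodesics from `v` downward
  in the BFS dag satisfies `ψ(v) = Σ_{w : v ∈ pred(w)} (1 + ψ(w))`, and
  `σ_sv · ψ(v)` summed over sources (halved) is the number of geodesics
  through `v`. Stress is reported raw: on real interactomes it takes
  values in the tens of thousands, and that scale is how the metric is
  conventionally tabulated.

The test suite checks both path metrics against an independent oracle
that enumerates every geodesic explicitly — exhaustively on all labeled
connected graphs of up to 6 nodes (27,474 graphs), on 200 seeded 7-node
graphs spanning densities 0.25–0.8, and on 50 seeded 8–9-node graphs.
Exhausting 7-node graphs outright would mean 2^21 labeled graphs; since
both the metrics and the oracle are invariant under relabeling, the
seeded sample over density classes covers the same ground at a size a
test suite can afford. These sizes are the package's chosen trade-off
between coverage and runtime.

### The selection cascade

* **hubs**: `degree > mean + k·sd`, default `k = 2`, *sample* standard
  deviation, *strict* inequality. Strictness makes a degree-regular
  component hub-free instead of arbitrary; the sample SD is the common
  statistical default. Raising `k` can only shrink the hub set.
* **top-fraction lists** (bottlenecks by betweenness, plus closeness and
  stress lists): target count `⌈n·fraction⌉` with default fraction 0.05.
  Ceiling (rather than floor) is what makes a 232-node component yield
  12-entry top-5% lists. Genes tied with the last admitted value are all
  admitted — a tie is never silently truncated — with a logged note.
* **hub-bottlenecks**: intersection of hubs and bottlenecks, hub
  (degree-rank) order preserved. **Crucial genes**: hub-bottlenecks also
  present in both the closeness and stress lists. The containment chain
  `crucial ⊆ hub-bottlenecks ⊆ hubs` is asserted at pipeline write time
  on every run.
* **tiering**: the potent/moderate/weak grouping of crucial genes is a
  narrative judgement in the literature; `tier_crucial()` encodes it as
  a deterministic rule. Genes tied at the minimum degree are *weak*
  (provided a gene remains above them); among the remaining genes sorted
  by degree descending, everything above the largest consecutive gap
  (first occurrence from the top, so the potent tier is as small as the
  rule allows) is *potent*; the rest are *moderate*. All-equal degrees
  give all-moderate; a single gene left above the weak tier is potent;
  fewer than three crucial genes cannot be split three ways and are all
  potent, with a warning. On the embedded reference degrees
  (110, 103, 102, 82, 81, 76, 71, 69, 64, 64) the largest gap is
  102 → 82 and the rule yields 3 potent / 5 moderate / 2 weak. An
  explicit `tier_override` replaces computed tiers when a curated
  assignment is preferred.

### Scale-free assessment

Power laws `y = a·x^b` are fitted by least squares on `(ln x, ln y)`.
Two statistics are reported because the convention in network-analysis
tools yields two distinct ones: `correlation` is Pearson's r on the
*untransformed* points and `r_squared` is the coefficient of
determination of the log-log line. The degree fit uses the degree
histogram directly (x = degree, y = count). Betweenness and closeness
are continuous, so their distributions are formed by grouping nodes into
equal-width bins over the metric range (default 20 bins; x = bin
midpoint, y = count). Zero values — e.g. the betweenness of leaves —
cannot enter a log fit and are excluded with a logged count. A constant
metric has no fittable distribution and is reported as not assessable
rather than erroring the whole report. The fit recovers exact power-law
data to 1e−9 relative error across exponents in [−3, 3] and is
scale-covariant (scaling y scales `a`, leaves `b` and R² unchanged).
Maximum-likelihood power-law estimation (Clauset-style, with x_min
search and goodness-of-fit p-values) is deliberately out of scope: the
reference analysis style is the plain log-log regression, and the
package reproduces that.

### MCODE-style clustering

The clustering reconstructs the classic molecular-complex detection
(MCODE) procedure, the standard choice for dense-module discovery in PPI
networks: each node is weighted by the density of the highest k-core of
its closed neighborhood times that core's order (0 when the neighborhood
has no 2-core, so tree-like regions never seed); clusters grow
breadth-first from the highest-weight unvisited seed, admitting
neighbors with weight `≥ seed_weight · (1 − node_score_cutoff)`; the
haircut removes singly-connected members, iterated to a fixed point
(equivalently, the cluster is trimmed to its 2-core — iteration, rather
than a single pass, is what makes growth monotone in the cutoff); and
clusters must contain a core of order `k_core`. Defaults — cutoff 0.2,
k-core 2, haircut on, no fluff expansion, depth limit 100 — are the
conventional desktop-tool defaults. Ranking is by score = density ×
size, with deterministic tie-breaking (size, then smallest member), and
clusters are disjoint. Recovery is validated on planted ground truth: a
K20 planted in a 200-node sparse background (edge probability 0.03) is
recovered to ≥ 19/20 members by the rank-1 cluster in every tested seed.

## The synthetic-data generator

`generate_network()` emulates the shape of the disease interactome the
pipeline targets: a scale-free main component with an exact node and
edge count plus an exact number of isolated genes (the default study
shape is 232 nodes / 2097 edges / 68 isolated). Standard preferential
attachment cannot hit an arbitrary edge count, so the component is grown
by preferential attachment at the nearest attachment rate and then
adjusted: degree-preferential edge additions, and random removals that
are rolled back whenever they would disconnect the component. The
connectivity check after every removal, and the exact isolated count,
are asserted by tests for every seed used. One seed drives all
randomness through R's RNG, and the caller's RNG state is restored
afterwards.

What the generator does *not* emulate: real interactome degree mixing,
clique-rich complex structure, confidence-score distributions (requested
scores are simply uniform on [400, 999]), or any biological identity of
the nodes (labels are `G0001`-style). Passing tests on synthetic
networks therefore demonstrate algorithmic correctness and shape
fidelity, not biological validity of any particular gene list. The
embedded reference tables (`coad_tables()`) carry the only real gene
symbols in the package and exercise the intersection and tiering stages
on published-scale values; the centrality values in that table are tied
to the exact database release behind the original network and are
treated as illustrative inputs, not as regression targets recomputable
from scratch.

## Numerical and degenerate-input choices

* Node identifiers are case-sensitive verbatim strings; no symbol
  normalization or identifier mapping is attempted.
* Duplicate scored edges keep the maximum score; `min_score` filtering
  happens after collapsing, and endpoints of removed edges remain as
  isolated nodes.
* Betweenness normalization requires n ≥ 3, closeness n ≥ 2; degree-0
  input is rejected by all component-restricted metrics and never by
  degree itself.
* Empty selections, header-only tables and empty cluster sets are legal
  outputs, not errors; infeasible generator requests and malformed input
  lines fail fast with the offending bound or line number.
* The pipeline writes deterministic TSV/JSON artifacts; rerunning with
  the same config and seed is byte-identical.

## Problem sizes

The default test and acceptance workloads are sized for a laptop-class
single core: exhaustive oracle comparison up to 6 nodes plus 250 seeded
7–9-node graphs (about two minutes), 20 seeds each for the
preferential-attachment exponent sign (n = 500) and planted-K20
recovery (n = 200), and a 232-node component for the end-to-end
workflow. All of these scale linearly in the number of seeds if stronger
evidence is wanted.

## Known limitations

* Betweenness and stress are exact, serial, O(n·m); components beyond a
  few thousand nodes would want a compiled or sampled implementation.
* The tie between the reference tables and any *recomputable* network is
  by construction loose: the source database evolves, so the package
  treats printed gene lists as inputs rather than attempting to
  re-derive them from a live download.
* Cluster membership is hard (no overlap); algorithms that share nodes
  between complexes (fluff expansion, fuzzy clustering) are not
  implemented.
* Only unweighted geodesics are considered; score-weighted centralities
  are out of scope.
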