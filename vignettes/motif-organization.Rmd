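---
title: "Quantifying motif organization in directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motif organization in directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifclust)
library(igraph)
```

## The problem

Network motifs — small subgraphs such as the feed-forward loop (FFL:
input A regulates intermediate B and output C, with B also regulating C) —
are statistically overrepresented building blocks of regulatory,
metabolic, neural, ecological, and engineered networks. Counting motifs
alone says nothing about how they are *assembled*: whether they sit in
isolation or aggregate by sharing nodes, and in which geometric
arrangements. This package quantifies that organization for simple
directed graphs.

Throughout, motif occurrences use **induced** matching semantics: the
subgraph induced by a candidate node set must carry exactly the pattern's
edges and no others. This is the standard motif-census convention, and it
is the only choice under which two FFLs sharing one node always have a
six-edge union, two FFLs sharing two nodes a five-edge union, and exactly
12 pairwise clustering types exist. It is applied consistently in the
instance search, the type catalog, and the null models. A corollary worth
knowing: an instance is identified by its node set (a node set can host at
most one induced instance per pattern), which is how automorphic role
assignments (e.g. the three rotations of a feedback loop) collapse to a
single occurrence.

## The motif clustering coefficient

Given the set of found instances $F = \{f_1,\dots,f_n\}$ (node sets), the
motif clustering coefficient is

$$M_c = \frac{S}{T}, \qquad
S = \sum_{i<j} |f_i \cap f_j|, \qquad
T = \sum_{i<j} \big(\min(|f_i|,|f_j|) - 1\big).$$

$T$ is the ceiling: two *distinct* instances of a size-$m$ motif can share
at most $m-1$ nodes, so for a single 3-node pattern
$T = \binom{n}{2} \cdot 2$. $M_c = 0$ means all instances are
node-disjoint; $M_c = 1$ means every pair shares the maximum possible.
With several pattern types, the homologous coefficient $M_c^+$ pools
same-type pairs and the heterologous $M_c^\pm$ pools cross-type pairs. Two
numerical conventions matter:

* the $-1$ in the denominator is applied **per pair** (inside the sum) in
  the mixed-type case as well, which is the only reading consistent with
  the single-type closed form;
* an undefined ratio ($T = 0$, e.g. fewer than two instances) is reported
  as `NaN` with a warning, never as 0 — 0 is the meaningful "fully
  isolated" value.

## The clustering-type catalog

`enumerate_types()` constructs every graph obtainable as the union of two
pattern copies identified on one or more shared nodes, subject to each
copy remaining induced in the union, and deduplicates by graph
isomorphism (BLISS canonical labeling). The induced requirement forbids,
for example, identifying an edge of one copy with the *reversed* edge of
the other, and is what makes the FFL catalog come out at exactly 12
types: 6 one-node-sharing (5 nodes, 6 edges) and 6 two-node-sharing
(4 nodes, 5 edges). For the 3-cycle feedback loop, whose rotational
symmetry collapses the possibilities, there are exactly 2.

FFL type ids follow the conventional numbering, anchored on role pairs
(with the one-node types 1–6 ordered (C,C), (B,C), (A,C), (B,B), (A,B),
(A,A) and the two-node types 7–12 ordered (BC,BC), (AB,AC), (AB,BC),
(AC,AC), (AC,BC), (AB,AB)). The anchors fix all the semantically loaded
ids: type 6 is the shared-input star, type 4 the shared-intermediate
relay, types 7/10/12 are the unions produced by duplicating the input,
intermediate, and output node respectively, and type 9 is the three-level
hierarchy. For any other pattern set a documented generic order is used:
shared-node count ascending, then canonical certificate. This puts the
single-shared-node feedback-loop type at id 1 and the shared-edge type at
id 2.

Pair classification (`classify_pair()`, used by `type_distribution()`)
builds the union of the two instances' *own* edges — not the induced graph
on their combined node set — so bystander edges between non-shared nodes
cannot break classification; this guarantees every clustered pair maps to
exactly one catalog entry. Because the catalog is enumerated from role
identifications, classification is implemented as an O(1) lookup of the
shared nodes' role configuration; the isomorphism route is retained as a
fallback and as the independent oracle in the test suite. Both routes are
provably equivalent: any two network instances are induced in their pair
union, so their configuration always occurs among the enumerated
candidates.

```{r catalog}
catalog <- enumerate_types(motif_ffl())
catalog$table[, c("id", "shared", "roles_a", "roles_b", "n_edges")]
```

## Per-node measures

**Motif clustering diversity (MCD).** The MCD of a node is the number of
*distinct* clustering types among the pairs of instances that contain the
node (the node lies in both instances of the pair). Many pairs of one type
count once: the hub of a shared-input star has MCD 1 no matter how many
FFLs hang off it. MCD is bounded by the catalog size (12 for FFLs) and is
the package's predictor of functionally important, cross-cluster
coordinating nodes.

**Node spin.** $\mathrm{spin}(v) = (k_{in} - k_{out})/(k_{in} + k_{out})$:
$-1$ for pure sources (producers), $+1$ for pure sinks (receivers), 0 for
balanced relays. The sign convention follows the in-minus-out definition;
it is stated prominently because a reader comparing histograms should know
which side is which. Isolated nodes have undefined spin and are excluded
from histograms with a logged count. The default histogram uses 21 bins so
that $-1$, $0$, $+1$ fall on bin centers (bin width 0.1).

## Null models

Four generators support significance and robustness questions:

* `erdos_renyi(n, p)` — each ordered pair is an edge independently with
  probability $p$. Under this model the expected induced-FFL count is
  $6\binom{n}{3}p^3(1-p)^3$, which the tests use as a closed-form
  calibration.
* `duplication_growth(template, target_n)` — repeatedly duplicates a node
  with its full in/out neighborhood (no edge to the originator, since
  only existing associated edges are copied). Duplicating a motif member
  creates a new same-type instance fully clustered with the original, so
  the model leaves a signature: mass on the duplication types 7, 10, 12
  (and, among one-node types, only on the same-role pairs 1, 4, 6).
  `role_bias` makes the choice non-uniform per role lineage, emulating
  biased duplication.
* `degree_preserving_randomize()` — directed double-edge swaps rejecting
  self-loops and duplicates; both degree sequences are preserved exactly.
  The default attempts 10 swaps per edge, a common mixing heuristic.
* `motif_preserving_sample()` — rejection sampling of networks with the
  same node, edge, *and motif* count: place motif copies on uniform
  distinct node tuples until the census matches, then fill in the
  remaining edges uniformly; any state exceeding the target motif or edge
  count triggers a restart. One subtlety is not in the original recipe:
  under induced semantics an added edge can also *destroy* instances, so
  a completed candidate is additionally rejected unless its final census
  equals the target. The restart budget (default 10,000) is configurable
  and the consumed restarts are reported.

`motif_significance()` wires these together: motif counts are tested
against the degree-preserving null, $M_c$ against the motif-preserving
null (so clustering significance is conditional on the motif count), with
$z = (x_{obs} - \bar x_{null})/s_{null}$ (sample sd) and an empirical
upper-tail $P = (r+1)/(n+1)$. A degenerate null (sd 0) yields a signed
infinity sentinel with a warning rather than a silent division.
`edge_removal_robustness()` removes a fixed fraction of edges uniformly
(per trial), recomputes the type distribution, and averages fractions
across trials; trials left with no clustered pair contribute a zero
vector, a convention chosen so that the average reflects survival of
structure rather than being undefined.

## Label enrichment

`mcd_enrichment()` asks whether a binary node label (e.g. essentiality)
concentrates at particular MCD values while adjusting for very unequal
group sizes: each group's labeled count is modeled as fixed-margin
hypergeometric sampling (population $N$, $K$ labeled, draw $n_g$), giving
exact expectation and variance and hence a per-group z score. A label
permutation null (default 10,000 shuffles) is exposed as a cross-check
because the two standard deviations need not coincide in small groups.
`top_set_comparison()` contrasts top-$k$ selections by MCD, degree, and
normalized directed betweenness; ties at the threshold are all included
(threshold-inclusive selection, so the effective $k$ is reported), which
matches the practice of growing the set until it captures all nodes at
the top score.

## Synthetic fixtures

`make_type_fixture(type_id, k)` builds $k$ FFLs whose every clustered pair
realizes one prescribed type, with ground truth derived from the
construction arithmetic rather than from the package's own detector:
stars for types 1, 4, 6 (one shared node; $M_c = 1/2$), chains for types
2, 3, 5 (consecutive copies share one node; $M_c = 1/k$), two-node stars
for 7, 10, 12 ($M_c = 1$). Types 8, 9, 11 identify *different* role sets
in the two copies, so any third copy would create pairs of another type;
they are only constructible pairwise-pure at $k = 2$ and the function
refuses larger $k$ with an explanation. `make_mixed_fixture()` glues
node-disjoint two-motif blocks so a requested composition is achieved
exactly. These fixtures emulate clustering geometry only — they have none
of the degree heterogeneity, density, or noise of real networks, so
passing them validates the combinatorial machinery, not robustness to
real-data artifacts; the random-digraph oracle tests cover the latter.

```{r fixture}
fx <- make_type_fixture(6, k = 3)
motif_clustering(fx$network)
```

## Problem sizes and numerical choices

The package's own verification suite runs at deliberately desk-scale
sizes chosen to keep the brute-force oracles exact: random digraphs up to
25 nodes for oracle-equivalence checks, 200 seeds for the Erdos-Renyi
census calibration at $n = 50$, $p = 0.05$, 100 repetitions for the
z-score self-consistency check, duplication growth to 30 nodes, and 50
trials per fraction for edge-removal robustness on a 10-FFL fixture.
Canonical labeling of catalog graphs (at most 6 nodes here) is exact;
the test oracles use exhaustive permutation isomorphism instead, so the
two routes are independent. All stochastic entry points accept a seed and
are reproducible given it; seeds default to the session RNG rather than a
hidden constant.

## Limitations

* Only simple digraphs: weights, signs, multi-edges, and temporal
  information are out of scope, and self-loops are removed at load (with
  a logged count) because every definition above assumes their absence.
* Patterns beyond 4 nodes are untested territory: catalog enumeration and
  canonical labeling remain correct but instance search cost grows
  quickly, and the fixture recipes are FFL-specific.
* The rejection sampler's running time degrades on dense,
  motif-saturated networks (high rejection rate); the restart budget
  makes this fail loudly rather than hang.
* Analytic expected type distributions for the random models are not
  implemented; Monte-Carlo estimation with the same generators is used
  instead.
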