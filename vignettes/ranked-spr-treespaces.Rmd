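---
title: "Ranked SPR treespaces: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked SPR treespaces: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankedSPR)
```

## The objects: ranked trees and their cluster representation

A *ranked tree* is a rooted binary phylogenetic tree on leaves
$X = \{l_1, \dots, l_n\}$ whose internal nodes carry distinct ranks
$1, \dots, n-1$ that increase towards the root, while all leaves sit at
rank 0. Ranked trees are the discrete skeleton of ultrametric time trees:
the rank order of internal nodes is the order of the coalescence events,
with the actual event times forgotten. A ranked tree is uniquely encoded by
its *cluster representation* — the list $[C_1, \dots, C_{n-1}]$ of leaf
sets below each internal node, ordered by rank — and this list is the
package's canonical store:

```{r}
T5 <- rankedTree(list(c("l1", "l2"), c("l1", "l2", "l3"), c("l4", "l5")))
T5
```

Internally each cluster is a bit mask over the sorted leaf labels, which
caps trees at 31 leaves; every algorithm in the package is exponential in
`n` long before that limit matters. Validity is checked by replaying the
merge sequence the clusters encode: starting from singleton blocks, the
cluster at each rank must be the disjoint union of exactly two current
blocks. This single invariant enforces binarity and the compatibility of
ranks with the ancestor relation at once. The root cluster is always stored
(and written), but parsers accept input with or without it since both
dialects are in circulation.

Two equivalent derived views are provided. The *labeled edge set* names
every node by its rank (internal) or its label (leaf) and lists the
$2(n-1)$ parent–child pairs; `edgeSet()` and `treeFromEdges()` are mutually
inverse. The *unranked topology* (`unrankedTopology()`) forgets the rank
order and keeps the laminar family of clusters.

## The moves

An *HSPR move at rank $i$* (horizontal SPR) prunes one child subtree of the
internal node of rank $i$ and reattaches it — at the same rank $i$ — on an
edge $(j^+, j^-)$ that *covers* rank $i$, i.e. $j^- \prec i \prec j^+$ in
the rank order. Reattachment above the root is not allowed. The move is the
discrete analogue of the fixed-height prune-and-regraft proposals used by
Bayesian time-tree samplers, which is what motivates studying the geometry
it induces. A *rank move* swaps the ranks of two consecutive-rank nodes not
joined by an edge (a *rank interval*). HSPR moves alone generate **HSPR
space**; HSPR plus rank moves generate **RSPR space**.

Moves are applied in two independently coded forms: an edge-set rewrite
(remove $(i^+,i), (i,i^-), (j^+,j^-)$; add $(i^+,i^-), (j^+,i), (i,j^-)$)
and a cluster rewrite (new cluster $B \cup C$ at rank $i$; above $i$,
clusters containing the moved block $B$ but not the target block $C$ lose
$B$, clusters containing $C$ gain $B$). The cluster form is the fast path;
the edge form exists purely so that the test suite can check the two
against each other, exhaustively for $n \le 5$ and on random larger trees.
A tree on $n \ge 3$ leaves always has exactly $(n-1)(n-2)$ HSPR neighbours
and $(n-1)(n-2) + k$ RSPR neighbours, $k$ its number of rank intervals; the
suite verifies these counts against brute-force enumeration.

```{r}
length(treeNeighbors(T5, "hspr"))
rankIntervals(T5)
```

## Distances, bounds, and paths

Exact distances are computed by bidirectional breadth-first search over the
move graph (`treeDistance()`), expanding the smaller frontier and keying
vertices by their canonical cluster-list string. No polynomial algorithm is
known for either metric — whether distance computation is NP-hard here is
open — so BFS is guarded by a leaf budget (`maxLeaves = 8` by default, a
deliberate compromise: distances stay small, but neighbourhoods grow
quadratically and frontier sizes exponentially).

Two cheap proxies bracket the exact distance:

* `bottomUpPath()` builds an explicit HSPR path by fixing the target's
  clusters rank by rank from the bottom, at most two moves per rank, hence
  at most $2(n-2)$ moves. It certifies connectivity of both spaces and is
  an upper bound, *not* the distance — the suite exhibits 5-leaf pairs
  where it overshoots.
* `leafParentBound()` counts the leaves whose parent ranks differ; one HSPR
  move can repair at most two of them, so $\lceil x/2 \rceil$ is a lower
  bound.

`allShortestPaths()` enumerates every geodesic (BFS distance labels, then
backward traversal of the geodesic DAG), in a deterministic order —
lexicographic in the serialized move sequences — so that downstream audits
are reproducible. `rankMoveDistance()` is BFS restricted to rank moves,
defined within one unranked topology.

Two path transforms reshape geodesics without changing endpoints or length:
`monotoneRankPath()` repeatedly swaps adjacent HSPR moves at decreasing
ranks, and `normalizeRankFirst()` pushes all rank moves of an RSPR path to
its front. Both rely on local exchange properties of the move calculus. We
deliberately implement each local exchange by *searching* for the single
intermediate tree (over the at most $(n-1)(n-2) + k$ candidates) rather
than transcribing the case-by-case edge rewrites that prove the exchanges
exist: the search has the same contract, is far less error-prone, and turns
the existence claims into falsifiable assertions — if no intermediate
exists the package raises `NoIntermediateFound`, which the test suite
treats as a failure. `cyclePath()` constructs the explicit length-$d$ path
that cyclically permutes $d$ disjoint subtree attachments (all attachment
ranks above all subtree ranks), the workhorse behind distance collapses.

## Whole treespaces at small n

`buildTreespace()` enumerates all $n!(n-1)!/2^{n-1}$ ranked trees via their
merge sequences (a bijection, so no deduplication is needed) and
precomputes adjacency into index arrays before any sweep. At $n = 7$ that
is 56,700 trees and about 1.7M directed HSPR edges, held comfortably in
memory as integer vectors.

Eccentricity is invariant under leaf relabelling, which is a graph
automorphism of both spaces. `treespaceDiameter()` therefore runs one BFS
per *shape* — the orbit of a tree under leaf permutations, keyed by
renaming leaves in order of first appearance in the cluster list (leaves
that first appear together do so as an exchangeable cherry, so the key is
well defined). At $n = 7$ this reduces 56,700 BFS runs to 61, one per
shape, and the whole diameter computation takes well under a minute. The
computed values follow $\lfloor 3(n-2)/2 \rfloor$ for $n \le 7$; the
package computes, it does not assume — whether the formula persists for
larger $n$ is open.

`auditTreespace()` packages the exhaustive structural checks as named,
machine-checkable properties returning an `auditReport` (instances checked,
violations, witnesses). Two design points deserve mention:

* **Vertex-form geodesic checks.** A vertex $v$ lies on some geodesic from
  $T$ to $R$ iff $d(T,v) + d(v,R) = d(T,R)$. Properties of the form "every
  tree on every shortest path has X" (cherry preservation, cluster-prefix
  preservation) are therefore checked per on-geodesic *vertex* against the
  all-pairs distance matrix, avoiding path enumeration entirely.
* **Existence of monotone geodesics** is decided by dynamic programming
  over the geodesic DAG: process vertices by increasing distance to the
  target and record the maximum feasible first-move rank of a monotone
  geodesic from each vertex. This checks all ordered pairs at $n = 5$
  (32,220 of them) in seconds, where naive geodesic enumeration blows up.

The audits cover: the neighbourhood-size formulas ($n \le 6$),
connectivity, the failure of the weak cluster property (the 5-leaf pair
sharing $\{l_4, l_5\}$ that no geodesic in either space preserves),
preservation of shared rank-one cherries and of shared cluster prefixes on
all geodesics, distance invariance under deletion of a shared cherry leaf,
non-repetition of moved subtrees on fixed-rank geodesics, equality of the
two metrics between caterpillar endpoints, rank-first normalizability of
all RSPR geodesics, the existence of distance-equalizing rankings for any
pair of unranked topologies, and the leaf-addition distance collapse
(below).

## Leaf addition can collapse distances

The rotated caterpillar pair (`lemmaCaterpillarPair(n)`) — the caterpillar
$(l_1, \dots, l_n)$ against the caterpillar $(l_2, \dots, l_n)$ with $l_1$
attached just below the root — keeps the parents of all leaves but $l_2$
at different ranks, forcing distance at least $\lceil (n-1)/2 \rceil$ in
both metrics. Yet adding one leaf $l_{n+1}$ — above the root of the first
tree, and as a rank-one cherry partner of $l_1$ in the second
(`addLeaf()`) — produces trees that are a *single* HSPR move apart: the
move prunes $l_1$ at rank one and reattaches it next to $l_{n+1}$. Distance
in these spaces is thus not monotone under leaf addition, a "rogue taxon"
effect with direct consequences for comparing time trees that differ in
unstable leaves. `isOneSpr()` closes the circle: whenever two ranked trees
are one HSPR move apart, their unranked topologies are at most one rooted
SPR move apart, which the package checks by enumerating the full rooted SPR
one-neighbourhood (including regrafts above the root).

```{r}
pair <- lemmaCaterpillarPair(6)
grown <- list(T = addLeaf(pair$T, "l7", "above_root"),
              R = addLeaf(pair$R, "l7", "rank_one_cherry", sibling = "l1"))
c(base = treeDistance(pair$T, pair$R, "hspr"),
  grown = treeDistance(grown$T, grown$R, "hspr"))
```

## Random generation and what the tests do (and do not) show

`randomRankedTree()` draws from the backward coalescent: at each rank a
uniformly chosen pair of current blocks merges. Every merge sequence then
has probability $2^{n-1} / (n!\,(n-1)!)$, i.e. the draw is uniform over
ranked labeled trees — an assumption the suite tests directly
(chi-squared uniformity at $n = 3$, coverage of all 18 trees at $n = 4$).
Randomized checks in the suite use trees of 4–9 leaves under fixed seeds.

These generated trees are combinatorial objects, not data. They emulate
the discrete structure of time trees — binary, ultrametric, strictly
ordered events — and nothing else: no branch-length noise, no sampling
through time, no polytomies, no estimation uncertainty. Passing tests
therefore certify the combinatorics and the algorithms on the stated
domain, not behaviour on inferred trees whose heights are tied or
uncertain; such trees must first be resolved to a strict rank order.

## Numerical and interface choices

* **Newick dialect.** Leaves at height 0, internal node of rank $i$ at
  height $i$, branch length = rank difference; integer heights round-trip
  exactly. Real-valued ultrametric input is accepted and rank-ordered;
  leaf-height deviations beyond `tol` ($10^{-8}$ by default) raise
  `NotUltrametric`, and internal heights closer than `tol` raise
  `TiedInternalHeights` rather than being broken arbitrarily — a tie is
  ambiguous data, not a formatting detail.
* **Determinism.** Move enumeration is sorted (rank, pruned-child label,
  attach-edge labels; rank moves last), geodesic lists are sorted by move
  serialization, and cluster strings are canonical (sorted leaves, root
  emitted). Identical inputs and seeds give byte-identical outputs,
  including from the command-line interface in `exec/rankedspr`.
* **Degenerate inputs.** The 2-leaf space is a single vertex with empty
  neighbourhoods and distance 0. Moves at the root rank are invalid (no
  edge covers rank $n-1$). `cyclePath()` rejects cycles touching the root,
  repeated subtrees, or attachment structures whose intermediate moves
  fail validation.
* **Problem sizes.** Exhaustive work is sized to the combinatorics: all
  audits run at $n \le 5$ (or $n \le 6$ where only degrees are needed),
  and the one deliberately heavy computation — the $n = 7$ HSPR diameter —
  uses the orbit reduction described above. These sizes match what the
  underlying statements require (they are claims about small-$n$
  treespaces, or all-$n$ statements checked on their smallest nontrivial
  instances).

## Known limitations

The complexity of computing $d_{\mathrm{HSPR}}$ and $d_{\mathrm{RSPR}}$ is
unknown; this package offers exact BFS at small $n$ and the
bottom-up/lower-bound bracket beyond that, with no claim of polynomial
exactness. Sharpness of the $\lceil (n-1)/2 \rceil$ caterpillar bound is
open, so the audits assert only the inequality. The RSPR diameter has no
closed form here — only the sandwich between the leaf-parent bound and the
HSPR diameter. Non-binary trees, tied ranks, sampled ancestors and dated
tips are out of scope.
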