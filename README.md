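# rankedSPR

Treespaces of **ranked phylogenetic trees** under **horizontal subtree
prune and regraft**.

Time trees — phylogenies whose internal nodes are dated, as inferred by
BEAST-style Bayesian samplers — are compared and proposed-from using
rearrangement moves that respect node times. This package implements the
discrete core of that setting: *ranked trees* (rooted binary trees on
leaves `l1..ln` whose internal nodes carry distinct ranks `1..n-1`
increasing to the root) and two move graphs on them:

* **HSPR** — an HSPR move at rank *i* prunes a child subtree of the node
  of rank *i* and reattaches it at the same rank on an edge `(j⁺, j⁻)`
  covering that rank (`j⁻ ≺ i ≺ j⁺`); reattachment above the root is not
  allowed.
* **RSPR** — HSPR moves plus *rank moves*, which swap two
  consecutive-rank nodes not joined by an edge.

Both graphs are metric spaces on the `n!(n-1)!/2^(n-1)` ranked trees. A
tree is stored by its *cluster representation* `[C1, ..., C_{n-1}]` (leaf
sets below each internal node, by rank), on which a one-move rewrite has a
closed form; the labeled edge set `E(T)` is the equivalent dual view. The
package provides exact distances by breadth-first search, a bottom-up
`2(n-2)` path construction and the `⌈x/2⌉` leaf-parent lower bound,
geodesic enumeration and normalization (rank moves first; monotone move
ranks), exhaustive treespace graphs with orbit-reduced diameters, audits of
the spaces' structural properties (notably the failure of the weak cluster
property and the non-monotonicity of distance under leaf addition), and
parsers/writers for cluster-list text and ultrametric Newick. A CLI lives
in `exec/rankedspr`.

For users of time-tree inference: these are the spaces your SPR-type
proposals walk on, and their geometry (neighbourhood sizes, diameters,
what geodesics preserve) is what mixing and distance-based posterior
summaries inherit.

## A worked example

The 5-leaf pair that breaks the weak cluster property:

```r
library(rankedSPR)

T5 <- rankedTree(list(c("l1","l2"), c("l1","l2","l3"), c("l4","l5")))
R5 <- rankedTree(list(c("l4","l5"), c("l2","l3"), c("l1","l4","l5")))
T5
#> ranked tree on 5 leaves
#> [{l1,l2},{l1,l2,l3},{l4,l5},{l1,l2,l3,l4,l5}]

treeDistance(T5, R5, "hspr")
#> [1] 2
```

Both trees contain the cluster `{l4,l5}`, yet every length-2 geodesic
passes through a tree without it — here by moving `l1` next to `l4`, then
`l4` next to `l5`:

```r
allShortestPaths(T5, R5, "hspr")[[1]]
#> path of length 2
#>   [{l1,l2},{l1,l2,l3},{l4,l5},{l1,l2,l3,l4,l5}]
#>    -- HSPR(i=1, prune=l1, attach=(3,l4)) -->
#>   [{l1,l4},{l2,l3},{l1,l4,l5},{l1,l2,l3,l4,l5}]
#>    -- HSPR(i=1, prune=l4, attach=(3,l5)) -->
#>   [{l4,l5},{l2,l3},{l1,l4,l5},{l1,l2,l3,l4,l5}]
```

The first of those moves changes the parent ranks of exactly two leaves
(`l2` and `l5`), so the `⌈x/2⌉` lower bound is tight here:

```r
leafParentBound(T5, applyHspr(T5, hsprMove(1, "l1", c("3", "l5"))))
#> $x
#> [1] 2
#> $bound
#> [1] 1
```

Every 5-leaf tree has `(n-1)(n-2) = 12` HSPR neighbours, and the HSPR
diameter follows `⌊3(n-2)/2⌋` as far as exhaustive computation reaches:

```r
length(treeNeighbors(T5, "hspr"))
#> [1] 12
vapply(3:6, treespaceDiameter, 0L)
#> [1] 1 3 4 6
```

Adding a leaf can *decrease* distance. The rotated caterpillar pair on 6
leaves sits at distance 4, but after attaching `l7` (above one root, as a
rank-one cherry in the other) a single HSPR move connects the results:

```r
pair <- lemmaCaterpillarPair(6)
treeDistance(pair$T, pair$R, "hspr")
#> [1] 4
Tp <- addLeaf(pair$T, "l7", "above_root")
Rp <- addLeaf(pair$R, "l7", "rank_one_cherry", sibling = "l1")
treeDistance(Tp, Rp, "hspr")
#> [1] 1
```

The same computations from the shell:

```sh
exec/rankedspr distance "[{l1,l2},{l1,l2,l3},{l4,l5}]" "[{l4,l5},{l2,l3},{l1,l4,l5}]" --metric hspr --exact
# 2
exec/rankedspr diameter -n 4 --metric hspr
# 3
```

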