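# Ranked trees in cluster representation.
#
# A ranked tree on n leaves is stored as the list of clusters induced by its
# internal nodes, ordered by rank 1..n-1 (the root cluster, rank n-1, is
# always stored). Internally each cluster is a bit mask over the canonical
# leaf order, which keeps merge validation, move application and whole-space
# enumeration cheap; masks limit trees to 31 leaves, far beyond anything the
# exhaustive algorithms here can visit.

#' @keywords internal
rsprStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rankedSPR_error", "error", "condition")))
}

#' @keywords internal
popcount <- function(x) {
  n <- 0L
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' @keywords internal
maskOf <- function(members, labels) {
  idx <- match(members, labels)
  if (anyNA(idx)) {
    rsprStop("UnknownLeaf", paste0("unknown leaf label(s): ",
                                   paste(members[is.na(idx)], collapse = ", ")))
  }
  sum(bitwShiftL(1L, idx - 1L))
}

#' @keywords internal
maskMembers <- function(mask, labels) {
  labels[bitwAnd(bitwShiftR(mask, seq_along(labels) - 1L), 1L) == 1L]
}

# Simulate the rank-ordered merge sequence encoded by a cluster list.
# Returns the derived edge structure, or a validation failure.
#
# childMask / childId: 2 x (n-1), the two blocks merged at each rank.
# Node ids: positive i = internal node of rank i, negative j = leaf labels[j].
# parentRank: named by node id as character, rank of each node's parent
# (root excluded).
#' @keywords internal
treeStructure <- function(cl, n) {
  blocks <- bitwShiftL(1L, 0:(n - 1L))
  owners <- -(1:n)
  childMask <- matrix(0L, 2L, n - 1L)
  childId <- matrix(0L, 2L, n - 1L)
  parentRank <- integer(2L * n - 2L)  # positions: 1..n leaves, n+1..2n-2 ranks 1..n-2
  for (i in seq_len(n - 1L)) {
    inside <- bitwAnd(blocks, cl[i]) == blocks
    if (sum(inside) != 2L) {
      return(list(ok = FALSE,
                  why = sprintf("cluster at rank %d is not the union of exactly two blocks", i)))
    }
    sel <- which(inside)
    if (bitwOr(blocks[sel[1L]], blocks[sel[2L]]) != cl[i]) {
      return(list(ok = FALSE,
                  why = sprintf("cluster at rank %d is not the disjoint union of its blocks", i)))
    }
    childMask[, i] <- blocks[sel]
    childId[, i] <- owners[sel]
    for (id in owners[sel]) {
      pos <- if (id < 0L) -id else n + id
      parentRank[pos] <- i
    }
    blocks <- c(blocks[-sel], cl[i])
    owners <- c(owners[-sel], i)
  }
  internalParent <- if (n == 2L) NA_integer_ else
    c(parentRank[(n + 1L):(2L * n - 2L)], NA_integer_)
  list(ok = TRUE, childMask = childMask, childId = childId,
       leafParent = parentRank[1:n],
       internalParent = internalParent)
}

#' @keywords internal
validMasks <- function(cl, n) {
  st <- treeStructure(cl, n)
  st$ok
}

#' Construct a ranked tree from its cluster representation
#'
#' A ranked tree on leaves `X` is uniquely encoded by the list of clusters
#' (leaf sets below each internal node) ordered by increasing rank. The root
#' cluster (all leaves) may be omitted from the input and is then appended;
#' it is always part of the stored representation.
#'
#' @param clusters a list of character vectors, the clusters in ascending
#'   rank order, or a single string in cluster-list text format (see
#'   [parseClusterList()]).
#' @param leaves optional character vector of leaf labels; defaults to the
#'   union of the clusters. Labels must be distinct and must not collide with
#'   the internal rank labels `1..n-1`.
#' @return an object of class `rankedTree`.
#' @examples
#' rankedTree(list(c("l1", "l2"), c("l1", "l2", "l3"), c("l4", "l5")))
#' @export
rankedTree <- function(clusters, leaves = NULL) {
  if (is.character(clusters) && length(clusters) == 1L) {
    return(parseClusterList(clusters, leaves = leaves))
  }
  if (!is.list(clusters) || length(clusters) == 0L) {
    rsprStop("EmptyInput", "clusters must be a nonempty list of leaf sets")
  }
  for (cc in clusters) {
    if (length(cc) == 0L) rsprStop("EmptyInput", "empty cluster in input")
    if (anyDuplicated(cc)) rsprStop("DuplicateLeaf", "duplicated leaf inside a cluster")
  }
  if (is.null(leaves)) leaves <- unique(unlist(clusters))
  if (anyDuplicated(leaves)) rsprStop("DuplicateLeaf", "duplicated leaf label")
  labels <- leaves[order(leaves)]
  n <- length(labels)
  if (n < 2L) rsprStop("EmptyInput", "a ranked tree needs at least two leaves")
  if (any(labels %in% as.character(seq_len(n - 1L)))) {
    rsprStop("LabelClash", "leaf labels must be disjoint from rank labels 1..n-1")
  }
  cl <- vapply(clusters, maskOf, integer(1L), labels = labels)
  full <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  if (cl[length(cl)] != full) cl <- c(cl, full)
  if (length(cl) != n - 1L) {
    rsprStop("MergeInvalid",
             sprintf("expected %d clusters for %d leaves, got %d", n - 1L, n, length(cl)))
  }
  st <- treeStructure(cl, n)
  if (!st$ok) rsprStop("MergeInvalid", st$why)
  newRankedTree(labels, cl)
}

#' @keywords internal
newRankedTree <- function(labels, cl) {
  structure(list(labels = labels, clusters = as.integer(cl)),
            class = "rankedTree")
}

#' Number of leaves of a ranked tree
#' @param tree a `rankedTree`.
#' @return integer.
#' @export
nLeaves <- function(tree) length(tree$labels)

#' Leaf labels of a ranked tree
#' @param tree a `rankedTree`.
#' @return character vector in canonical (sorted) order.
#' @export
leafLabels <- function(tree) tree$labels

#' Clusters of a ranked tree
#' @param tree a `rankedTree`.
#' @return list of character vectors, ascending by rank, root included.
#' @export
clusterList <- function(tree) {
  lapply(tree$clusters, maskMembers, labels = tree$labels)
}

#' Canonical cluster-list string of a ranked tree
#'
#' The text format used throughout: `[{l1,l2},{l1,l2,l3},...]`, clusters in
#' ascending rank order, leaves sorted inside each cluster, root emitted.
#' @param tree a `rankedTree`.
#' @return a single string.
#' @export
clusterString <- function(tree) {
  paste0("[", paste0("{", vapply(clusterList(tree), paste, "", collapse = ","), "}",
                     collapse = ","), "]")
}

#' @export
print.rankedTree <- function(x, ...) {
  cat(sprintf("ranked tree on %d leaves\n%s\n", nLeaves(x), clusterString(x)))
  invisible(x)
}

#' @export
format.rankedTree <- function(x, ...) clusterString(x)

#' Test two ranked trees for identity
#'
#' Two ranked trees are identical when a leaf-label and rank preserving
#' isomorphism exists, which in cluster representation reduces to equality
#' of leaf sets and cluster lists.
#' @param a,b `rankedTree` objects.
#' @return logical.
#' @export
treeEqual <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$clusters, b$clusters)
}

#' @keywords internal
sameLeafSet <- function(a, b) identical(a$labels, b$labels)

#' @keywords internal
requireSameLeaves <- function(a, b) {
  if (!sameLeafSet(a, b)) rsprStop("LeafSetMismatch", "trees have different leaf sets")
  invisible(TRUE)
}

# --- node / label helpers -------------------------------------------------

# rank of the node addressed by a label: 0 for leaves, i for internal node i
#' @keywords internal
labelRankOf <- function(tree, lab) {
  if (lab %in% tree$labels) return(0L)
  i <- suppressWarnings(as.integer(lab))
  if (is.na(i) || i < 1L || i > nLeaves(tree) - 1L) {
    rsprStop("UnknownLeaf", paste0("no node with label ", lab))
  }
  i
}

#' @keywords internal
labelMaskOf <- function(tree, lab) {
  r <- labelRankOf(tree, lab)
  if (r == 0L) maskOf(lab, tree$labels) else tree$clusters[r]
}

# label of the node owning mask `m` given its id from treeStructure coding
#' @keywords internal
idLabel <- function(tree, id) {
  if (id < 0L) tree$labels[-id] else as.character(id)
}

# rank of the parent of the node with cluster/leaf mask m (m must not be root)
#' @keywords internal
parentRankOfMask <- function(cl, m) {
  cand <- which(bitwAnd(cl, m) == m & cl != m)
  if (length(cand) == 0L) NA_integer_ else cand[1L]
}

# --- derived representations ---------------------------------------------

#' Labeled edge set of a ranked tree
#'
#' Nodes are addressed by the label function: internal nodes by their rank,
#' leaves by their name. The edge set has `2(n-1)` parent–child pairs and
#' uniquely determines the tree (see [treeFromEdges()]).
#' @param tree a `rankedTree`.
#' @return a data.frame with character columns `parent` and `child`, ordered
#'   by parent rank then child label.
#' @export
edgeSet <- function(tree) {
  n <- nLeaves(tree)
  st <- treeStructure(tree$clusters, n)
  parent <- character(0)
  child <- character(0)
  for (i in seq_len(n - 1L)) {
    kids <- vapply(st$childId[, i], function(id) idLabel(tree, id), "")
    kids <- kids[order(kids)]
    parent <- c(parent, rep(as.character(i), 2L))
    child <- c(child, kids)
  }
  data.frame(parent = parent, child = child, stringsAsFactors = FALSE)
}

#' Rebuild a ranked tree from a labeled edge set
#'
#' Inverse of [edgeSet()]: accepts any data.frame (or 2-column matrix) of
#' parent/child labels where internal nodes are rank numbers and leaves are
#' names, and reconstructs the cluster representation.
#' @param edges data.frame with columns `parent`, `child`.
#' @return a `rankedTree`.
#' @export
treeFromEdges <- function(edges) {
  parent <- as.character(edges[[1L]])
  child <- as.character(edges[[2L]])
  ranks <- sort(unique(suppressWarnings(as.integer(parent))))
  if (anyNA(ranks) || length(ranks) == 0L || !identical(ranks, seq_along(ranks))) {
    rsprStop("ParseError", "edge parents must be the ranks 1..n-1")
  }
  m <- length(ranks)
  leaves <- setdiff(child, as.character(ranks))
  if (length(leaves) != m + 1L) {
    rsprStop("ParseError", "edge set is not that of a binary ranked tree")
  }
  labels <- leaves[order(leaves)]
  clusters <- vector("list", m)
  leafSetOf <- function(lab) {
    i <- suppressWarnings(as.integer(lab))
    if (!is.na(i) && as.character(i) == lab && i >= 1L && i <= m) clusters[[i]] else lab
  }
  for (i in seq_len(m)) {
    kids <- child[parent == as.character(i)]
    if (length(kids) != 2L) rsprStop("ParseError", "every internal node needs two children")
    clusters[[i]] <- unique(c(leafSetOf(kids[1L]), leafSetOf(kids[2L])))
  }
  rankedTree(clusters, leaves = labels)
}

#' Rank intervals of a ranked tree
#'
#' A rank interval `[r+1, r]` is a pair of internal nodes with consecutive
#' ranks that are not joined by an edge; these are exactly the positions at
#' which a rank move can be applied. Node `r+1` is parent of node `r` iff
#' the rank-`r` cluster is contained in the rank-`r+1` cluster.
#' @param tree a `rankedTree`.
#' @return a list of integer pairs `c(r+1, r)`, ascending by `r`.
#' @export
rankIntervals <- function(tree) {
  cl <- tree$clusters
  out <- list()
  for (r in seq_len(length(cl) - 1L)) {
    if (bitwAnd(cl[r], cl[r + 1L]) != cl[r]) {
      out[[length(out) + 1L]] <- c(r + 1L, r)
    }
  }
  out
}

#' Cherries of a ranked tree
#'
#' A cherry is an internal node whose two children are both leaves; in
#' cluster terms, a cluster of size two.
#' @param tree a `rankedTree`.
#' @return list of `list(leaves = <character(2)>, rank = <int>)`, ascending
#'   by rank.
#' @export
cherries <- function(tree) {
  sizes <- popcount(tree$clusters)
  lapply(which(sizes == 2L), function(i) {
    list(leaves = maskMembers(tree$clusters[i], tree$labels), rank = i)
  })
}

#' Caterpillar tree on an ordered leaf list
#'
#' The caterpillar on `(x1, ..., xn)` has clusters `{x1,x2}`,
#' `{x1,x2,x3}`, ..., `{x1,...,xn}`: every internal node of rank at least two
#' has the node of the previous rank as a child, so it has no rank intervals.
#' @param leaves character vector of at least two labels, in attachment order.
#' @return a `rankedTree`.
#' @export
caterpillarTree <- function(leaves) {
  if (length(leaves) < 2L) rsprStop("EmptyInput", "a caterpillar needs at least two leaves")
  rankedTree(lapply(seq_len(length(leaves) - 1L), function(i) leaves[1:(i + 1L)]),
             leaves = leaves)
}

#' Is a ranked tree a caterpillar?
#' @param tree a `rankedTree`.
#' @return logical: `TRUE` iff the tree has no rank interval.
#' @export
isCaterpillar <- function(tree) length(rankIntervals(tree)) == 0L

#' Delete a leaf of the rank-one cherry
#'
#' Removes `leaf` (which must be a child of the internal node of rank one),
#' suppresses that node and decrements all remaining ranks, yielding a tree
#' on n-1 leaves. This inverts [addLeaf()] with `mode = "rank_one_cherry"`.
#' @param tree a `rankedTree`.
#' @param leaf leaf label to delete.
#' @return a `rankedTree` on `n - 1` leaves.
#' @export
deleteCherryLeaf <- function(tree, leaf) {
  lm <- maskOf(leaf, tree$labels)
  if (bitwAnd(tree$clusters[1L], lm) != lm) {
    rsprStop("NotRankOneCherryLeaf",
             paste0(leaf, " is not a leaf of the cherry at rank one"))
  }
  keep <- setdiff(tree$labels, leaf)
  newClusters <- lapply(clusterList(tree)[-1L], setdiff, y = leaf)
  rankedTree(newClusters, leaves = keep)
}

#' Add a leaf to a ranked tree
#'
#' Two constructions:
#' * `mode = "above_root"`: a new root is introduced with the new leaf and
#'   the old root as children; all existing clusters are unchanged and the
#'   new root cluster is appended.
#' * `mode = "rank_one_cherry"`: the new leaf is attached as sibling of
#'   `sibling` with parent of rank one; all other internal nodes move up one
#'   rank, and every cluster containing `sibling` gains the new leaf.
#'
#' @param tree a `rankedTree`.
#' @param leaf new leaf label, not already present.
#' @param mode `"above_root"` or `"rank_one_cherry"`.
#' @param sibling existing leaf the new leaf pairs with (required for
#'   `rank_one_cherry`).
#' @return a `rankedTree` on `n + 1` leaves.
#' @export
addLeaf <- function(tree, leaf, mode = c("above_root", "rank_one_cherry"),
                    sibling = NULL) {
  mode <- match.arg(mode)
  if (leaf %in% tree$labels) rsprStop("DuplicateLeaf", paste0(leaf, " is already a leaf"))
  old <- clusterList(tree)
  if (mode == "above_root") {
    newClusters <- c(old, list(c(tree$labels, leaf)))
  } else {
    if (is.null(sibling) || !(sibling %in% tree$labels)) {
      rsprStop("UnknownSibling", "rank_one_cherry needs an existing leaf as sibling")
    }
    shifted <- lapply(old, function(cc) if (sibling %in% cc) c(cc, leaf) else cc)
    newClusters <- c(list(c(sibling, leaf)), shifted)
  }
  rankedTree(newClusters, leaves = c(tree$labels, leaf))
}

#' Forget ranks: the unranked topology of a ranked tree
#'
#' @param tree a `rankedTree` (or an `unrankedTopology`, returned as is).
#' @return an object of class `unrankedTopology`: the laminar family of
#'   clusters without rank order.
#' @export
unrankedTopology <- function(tree) {
  if (inherits(tree, "unrankedTopology")) return(tree)
  structure(list(labels = tree$labels, clusters = sort(tree$clusters)),
            class = "unrankedTopology")
}

#' @export
print.unrankedTopology <- function(x, ...) {
  sets <- vapply(x$clusters, function(m) {
    paste0("{", paste(maskMembers(m, x$labels), collapse = ","), "}")
  }, "")
  cat(sprintf("unranked rooted topology on %d leaves\n{%s}\n",
              length(x$labels), paste(sets, collapse = ",")))
  invisible(x)
}

#' Test two unranked topologies for equality
#' @param a,b `unrankedTopology` (or `rankedTree`) objects.
#' @return logical.
#' @export
topologyEqual <- function(a, b) {
  a <- unrankedTopology(a); b <- unrankedTopology(b)
  identical(a$labels, b$labels) && identical(a$clusters, b$clusters)
}

# --- enumeration and random generation ------------------------------------

#' Number of ranked trees on n labeled leaves
#' @param n number of leaves.
#' @return `n! (n-1)! / 2^(n-1)` as a double.
#' @export
countRankedTrees <- function(n) {
  factorial(n) * factorial(n - 1L) / 2^(n - 1L)
}

# All ranked trees on n leaves as a mask matrix (one row per tree, columns =
# ranks 1..n-1). Merge sequences are in bijection with ranked trees, so the
# recursion over unordered block pairs enumerates each tree exactly once.
#' @keywords internal
enumTreeMasks <- function(n) {
  if (n < 2L) rsprStop("EmptyInput", "need n >= 2")
  total <- countRankedTrees(n)
  M <- matrix(0L, nrow = total, ncol = n - 1L)
  row <- integer(n - 1L)
  idx <- 0L
  rec <- function(blocks, k) {
    if (k == n) {
      idx <<- idx + 1L
      M[idx, ] <<- row
      return(invisible(NULL))
    }
    nb <- length(blocks)
    for (a in seq_len(nb - 1L)) {
      for (b in (a + 1L):nb) {
        row[k] <<- blocks[a] + blocks[b]
        rec(c(blocks[-c(a, b)], blocks[a] + blocks[b]), k + 1L)
      }
    }
  }
  rec(bitwShiftL(1L, 0:(n - 1L)), 1L)
  M
}

#' Default leaf labels l1..ln
#' @param n number of leaves.
#' @return character vector.
#' @export
defaultLeaves <- function(n) paste0("l", seq_len(n))

#' Enumerate all ranked trees on a leaf set
#'
#' Exhaustive enumeration via merge sequences; the count is
#' `n!(n-1)!/2^(n-1)`, so this is practical for `n <= 7`.
#' @param n number of leaves (>= 2).
#' @param leaves optional labels, default `l1..ln`.
#' @return list of `rankedTree` objects, in a fixed deterministic order.
#' @export
enumerateTrees <- function(n, leaves = defaultLeaves(n)) {
  labels <- leaves[order(leaves)]
  M <- enumTreeMasks(n)
  lapply(seq_len(nrow(M)), function(i) newRankedTree(labels, M[i, ]))
}

#' Random ranked tree from the backward coalescent
#'
#' Starting from singleton blocks, a uniformly chosen pair of blocks is
#' merged at each rank. Every merge sequence has probability
#' `prod 1/choose(k,2) = 2^(n-1)/(n!(n-1)!)`, so the draw is uniform over
#' all ranked labeled trees.
#' @param n number of leaves (>= 2).
#' @param leaves optional labels, default `l1..ln`.
#' @param seed optional integer; if given, the RNG seed is set first so the
#'   same `(n, seed)` always returns the same tree.
#' @return a `rankedTree`.
#' @export
randomRankedTree <- function(n, leaves = defaultLeaves(n), seed = NULL) {
  if (n < 2L) rsprStop("EmptyInput", "need n >= 2")
  if (!is.null(seed)) set.seed(seed)
  labels <- leaves[order(leaves)]
  blocks <- bitwShiftL(1L, 0:(n - 1L))
  cl <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    sel <- if (length(blocks) == 2L) c(1L, 2L) else sample.int(length(blocks), 2L)
    cl[i] <- blocks[sel[1L]] + blocks[sel[2L]]
    blocks <- c(blocks[-sel], cl[i])
  }
  newRankedTree(labels, cl)
}
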