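# HSPR and rank moves.
#
# An HSPR move at rank i prunes one child subtree of the internal node of
# rank i and reattaches it, still below a node of rank i, on an edge that
# covers rank i. It is addressed by (rank, pruned child label, attach edge),
# which is minimal and invertible. A rank move swaps the ranks of two
# consecutive-rank internal nodes not joined by an edge.
#
# Application is implemented twice: on the labeled edge set and on the
# cluster representation. The two forms are provably equivalent and the
# test suite checks their agreement exhaustively on small trees.

#' Create an HSPR move record
#'
#' @param rank rank `i` of the move (the pruned subtree's parent).
#' @param prune label of the pruned subtree's root (leaf name or rank).
#' @param attach character vector `c(parent, child)` naming the reattachment
#'   edge, which must cover rank `i`.
#' @return an object of class `hsprMove`.
#' @export
hsprMove <- function(rank, prune, attach) {
  structure(list(rank = as.integer(rank), prune = as.character(prune),
                 attach = as.character(attach)),
            class = "hsprMove")
}

#' Create a rank move record
#' @param r lower rank: the move swaps the ranks of nodes `r` and `r+1`.
#' @return an object of class `rankMove`.
#' @export
rankMove <- function(r) structure(list(rank = as.integer(r)), class = "rankMove")

#' Serialize a move
#' @param m an `hsprMove` or `rankMove`.
#' @return a string like `HSPR(i=1, prune=l1, attach=(3,l5))` or `RANK(r=2)`.
#' @export
formatMove <- function(m) {
  if (inherits(m, "hsprMove")) {
    sprintf("HSPR(i=%d, prune=%s, attach=(%s,%s))", m$rank, m$prune,
            m$attach[1L], m$attach[2L])
  } else if (inherits(m, "rankMove")) {
    sprintf("RANK(r=%d)", m$rank)
  } else {
    rsprStop("InvalidMove", "not a move object")
  }
}

#' @export
print.hsprMove <- function(x, ...) { cat(formatMove(x), "\n"); invisible(x) }

#' @export
print.rankMove <- function(x, ...) { cat(formatMove(x), "\n"); invisible(x) }

#' Validate an HSPR move against a tree
#'
#' Checks the conditions under which the edge-set rewrite yields a tree:
#' `(i, prune)` must be an edge of the tree, the attach edge must be an edge
#' of the tree, and the attach edge must cover rank `i` (child strictly below
#' rank `i`, parent strictly above).
#' @param tree a `rankedTree`.
#' @param move an `hsprMove`.
#' @return character vector of violations; empty when the move is valid.
#' @export
validateHspr <- function(tree, move) {
  n <- nLeaves(tree)
  out <- character(0)
  i <- move$rank
  if (is.na(i) || i < 1L || i > n - 1L) {
    return(sprintf("rank %s outside 1..%d", as.character(move$rank), n - 1L))
  }
  st <- treeStructure(tree$clusters, n)
  kidLabs <- vapply(st$childId[, i], function(id) idLabel(tree, id), "")
  if (!(move$prune %in% kidLabs)) {
    out <- c(out, sprintf("(%d, %s) is not an edge of the tree", i, move$prune))
  }
  jp <- suppressWarnings(as.integer(move$attach[1L]))
  childLab <- move$attach[2L]
  childRank <- tryCatch(labelRankOf(tree, childLab), error = function(e) NA_integer_)
  if (is.na(jp) || is.na(childRank)) {
    return(c(out, "attach edge labels not found in the tree"))
  }
  # is the attach edge an edge of the tree?
  edgeOk <- jp >= 1L && jp <= n - 1L &&
    childLab %in% vapply(st$childId[, jp], function(id) idLabel(tree, id), "")
  if (!edgeOk) {
    out <- c(out, sprintf("(%s, %s) is not an edge of the tree",
                          move$attach[1L], move$attach[2L]))
  }
  if (!(childRank < i && i < jp)) {
    out <- c(out, sprintf("attach edge does not cover rank %d", i))
  }
  out
}

# Cluster-form rewrite on masks: new cluster B|C at rank i; above i, clusters
# containing B but not C lose B, clusters containing C gain B.
#' @keywords internal
applyHsprMask <- function(cl, i, B, C) {
  m <- length(cl)
  out <- cl
  out[i] <- bitwOr(B, C)
  if (i < m) {
    hi <- (i + 1L):m
    v <- cl[hi]
    hasB <- bitwAnd(v, B) == B
    hasC <- bitwAnd(v, C) == C
    v[hasB & !hasC] <- bitwAnd(v[hasB & !hasC], bitwNot(B))
    v[hasC] <- bitwOr(v[hasC], B)
    out[hi] <- v
  }
  out
}

#' Apply an HSPR move
#'
#' The move is validated, then applied either by the cluster-representation
#' rewrite (`form = "cluster"`, the default) or by the labeled edge-set
#' rewrite followed by reconstruction (`form = "edge"`). Both forms produce
#' the same tree; the edge form exists as an independent implementation used
#' for cross-checking.
#' @param tree a `rankedTree`.
#' @param move an `hsprMove`.
#' @param form `"cluster"` or `"edge"`.
#' @return the neighbouring `rankedTree`.
#' @export
applyHspr <- function(tree, move, form = c("cluster", "edge")) {
  form <- match.arg(form)
  bad <- validateHspr(tree, move)
  if (length(bad) > 0L) {
    rsprStop("InvalidMove", paste0("invalid HSPR move: ", paste(bad, collapse = "; ")))
  }
  if (form == "cluster") {
    B <- labelMaskOf(tree, move$prune)
    C <- labelMaskOf(tree, move$attach[2L])
    newRankedTree(tree$labels, applyHsprMask(tree$clusters, move$rank, B, C))
  } else {
    applyHsprEdgeForm(tree, move)
  }
}

#' @keywords internal
applyHsprEdgeForm <- function(tree, move) {
  n <- nLeaves(tree)
  st <- treeStructure(tree$clusters, n)
  i <- move$rank
  kidLabs <- vapply(st$childId[, i], function(id) idLabel(tree, id), "")
  iMinus <- setdiff(kidLabs, move$prune)
  if (length(iMinus) != 1L) iMinus <- kidLabs[kidLabs != move$prune][1L]
  iPlus <- as.character(st$internalParent[i])
  es <- edgeSet(tree)
  key <- paste(es$parent, es$child, sep = "\r")
  drop <- c(paste(iPlus, i, sep = "\r"),
            paste(i, iMinus, sep = "\r"),
            paste(move$attach[1L], move$attach[2L], sep = "\r"))
  es <- es[!(key %in% drop), , drop = FALSE]
  es <- rbind(es,
              data.frame(parent = c(iPlus, move$attach[1L], as.character(i)),
                         child = c(iMinus, as.character(i), move$attach[2L]),
                         stringsAsFactors = FALSE))
  treeFromEdges(es)
}

#' Apply a rank move
#'
#' Swaps the clusters at ranks `r` and `r+1`; only legal when `[r+1, r]` is
#' a rank interval (the two nodes are not joined by an edge). Applying the
#' same move twice returns the original tree.
#' @param tree a `rankedTree`.
#' @param move a `rankMove`, or an integer lower rank.
#' @return the neighbouring `rankedTree`.
#' @export
applyRankMove <- function(tree, move) {
  r <- if (inherits(move, "rankMove")) move$rank else as.integer(move)
  cl <- tree$clusters
  if (r < 1L || r > length(cl) - 1L) {
    rsprStop("NodesAdjacent", sprintf("no rank interval [%d, %d]", r + 1L, r))
  }
  if (bitwAnd(cl[r], cl[r + 1L]) == cl[r]) {
    rsprStop("NodesAdjacent",
             sprintf("nodes %d and %d are joined by an edge", r + 1L, r))
  }
  cl[c(r, r + 1L)] <- cl[c(r + 1L, r)]
  newRankedTree(tree$labels, cl)
}

# --- enumeration of all moves on a tree -----------------------------------

# Fast path used by treespace construction: all HSPR neighbours of a mask
# row, as a matrix (one neighbour per row). Order is deterministic but
# internal (by rank, child mask, attach mask).
#' @keywords internal
hsprNeighborMasks <- function(cl, n, st = treeStructure(cl, n)) {
  nodeMask <- c(bitwShiftL(1L, 0:(n - 1L)), cl)            # leaves, then ranks
  nodeRank <- c(integer(n), seq_len(n - 1L))
  parentRk <- c(st$leafParent, st$internalParent)
  out <- matrix(0L, nrow = (n - 1L) * (n - 2L), ncol = n - 1L)
  r <- 0L
  for (i in seq_len(n - 1L)) {
    cover <- which(nodeRank < i & !is.na(parentRk) & parentRk > i)
    if (length(cover) == 0L) next
    kids <- sort(st$childMask[, i])
    for (B in kids) {
      for (C in nodeMask[cover]) {
        r <- r + 1L
        out[r, ] <- applyHsprMask(cl, i, B, C)
      }
    }
  }
  out[seq_len(r), , drop = FALSE]
}

#' @keywords internal
rankNeighborMasks <- function(cl) {
  m <- length(cl)
  out <- list()
  for (r in seq_len(m - 1L)) {
    if (bitwAnd(cl[r], cl[r + 1L]) != cl[r]) {
      v <- cl
      v[c(r, r + 1L)] <- v[c(r + 1L, r)]
      out[[length(out) + 1L]] <- v
    }
  }
  if (length(out) == 0L) matrix(0L, 0L, m) else do.call(rbind, out)
}

#' Enumerate all moves applicable to a tree
#'
#' Returns every HSPR move (and for `metric = "rspr"` every rank move) on
#' the tree in a fixed deterministic order: HSPR moves ascending by rank,
#' then pruned-child label, then attach-edge labels; rank moves last,
#' ascending by rank. The deterministic order is what makes BFS parents and
#' path tie-breaking reproducible.
#' @param tree a `rankedTree`.
#' @param metric `"hspr"` or `"rspr"`.
#' @return list of move objects.
#' @export
neighborMoves <- function(tree, metric = c("hspr", "rspr")) {
  metric <- match.arg(metric)
  n <- nLeaves(tree)
  st <- treeStructure(tree$clusters, n)
  nodeLab <- c(tree$labels, as.character(seq_len(n - 1L)))
  nodeRank <- c(integer(n), seq_len(n - 1L))
  parentRk <- c(st$leafParent, st$internalParent)
  moves <- list()
  for (i in seq_len(n - 1L)) {
    cover <- which(nodeRank < i & !is.na(parentRk) & parentRk > i)
    if (length(cover) == 0L) next
    kids <- vapply(st$childId[, i], function(id) idLabel(tree, id), "")
    kids <- kids[order(kids)]
    cover <- cover[order(nodeLab[cover])]
    for (pr in kids) {
      for (cv in cover) {
        moves[[length(moves) + 1L]] <-
          hsprMove(i, pr, c(as.character(parentRk[cv]), nodeLab[cv]))
      }
    }
  }
  if (metric == "rspr") {
    for (iv in rankIntervals(tree)) {
      moves[[length(moves) + 1L]] <- rankMove(iv[2L])
    }
  }
  moves
}

#' Apply any move
#' @param tree a `rankedTree`.
#' @param move an `hsprMove` or `rankMove`.
#' @return a `rankedTree`.
#' @export
applyMove <- function(tree, move) {
  if (inherits(move, "hsprMove")) applyHspr(tree, move) else applyRankMove(tree, move)
}

#' One-move neighbourhood of a tree
#'
#' All distinct trees one move away. In HSPR space every tree on `n >= 3`
#' leaves has exactly `(n-1)(n-2)` neighbours; in RSPR space it has
#' `(n-1)(n-2) + k` where `k` is the number of rank intervals.
#' @param tree a `rankedTree`.
#' @param metric `"hspr"` or `"rspr"`.
#' @return list of `rankedTree` objects (deduplicated, the tree itself never
#'   included; the move enumeration order is preserved).
#' @export
treeNeighbors <- function(tree, metric = c("hspr", "rspr")) {
  metric <- match.arg(metric)
  nb <- lapply(neighborMoves(tree, metric), function(m) applyMove(tree, m))
  keys <- vapply(nb, function(t) paste(t$clusters, collapse = ","), "")
  nb <- nb[!duplicated(keys) & keys != paste(tree$clusters, collapse = ",")]
  nb
}

#' Identify the move connecting two adjacent trees
#'
#' @param a,b `rankedTree` objects one move apart.
#' @param metric `"hspr"` or `"rspr"`.
#' @return the first move (in [neighborMoves()] order) taking `a` to `b`.
#' @export
moveBetween <- function(a, b, metric = c("hspr", "rspr")) {
  metric <- match.arg(metric)
  requireSameLeaves(a, b)
  for (m in neighborMoves(a, metric)) {
    if (treeEqual(applyMove(a, m), b)) return(m)
  }
  rsprStop("InvalidMove", "trees are not connected by a single move")
}
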