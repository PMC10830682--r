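# Paths and distances in HSPR / RSPR space.
#
# Exact distances come from (bidirectional) breadth-first search over the
# move graph; the bottom-up construction gives a path of length <= 2(n-2)
# for any pair, and the leaf-parent count gives a matching-style lower
# bound ceil(x/2). Shortest-path enumeration and the two local path
# transforms (move-rank swap, rank-moves-first normalization) operate on
# explicit TreePath objects and re-validate everything they build.

#' A path of trees and moves
#'
#' @param trees list of `rankedTree` objects `[T_0, ..., T_d]`.
#' @param moves list of `d` move objects; `trees[[i+1]]` must equal
#'   `applyMove(trees[[i]], moves[[i]])`. Replay is checked on construction.
#' @return an object of class `treePath`.
#' @export
treePath <- function(trees, moves) {
  if (length(trees) != length(moves) + 1L) {
    rsprStop("InvalidMove", "a path of d moves needs d+1 trees")
  }
  for (i in seq_along(moves)) {
    if (!treeEqual(applyMove(trees[[i]], moves[[i]]), trees[[i + 1L]])) {
      rsprStop("InvalidMove", sprintf("path step %d does not replay", i))
    }
  }
  structure(list(trees = trees, moves = moves), class = "treePath")
}

#' Length of a tree path
#' @param path a `treePath`.
#' @return integer, the number of moves.
#' @export
pathLength <- function(path) length(path$moves)

#' @export
print.treePath <- function(x, ...) {
  cat(sprintf("path of length %d\n", pathLength(x)))
  cat(" ", clusterString(x$trees[[1L]]), "\n")
  for (i in seq_along(x$moves)) {
    cat("   --", formatMove(x$moves[[i]]), "-->\n")
    cat(" ", clusterString(x$trees[[i + 1L]]), "\n")
  }
  invisible(x)
}

# label of the node inducing mask m (leaf label or rank as character)
#' @keywords internal
maskLabel <- function(tree, m) {
  r <- which(tree$clusters == m)
  if (length(r) > 0L) return(as.character(r[1L]))
  lab <- maskMembers(m, tree$labels)
  if (length(lab) != 1L) rsprStop("UnknownLeaf", "mask does not address a node")
  lab
}

# --- bottom-up approximation (connectivity proof construction) -------------

#' Bottom-up HSPR path between two trees
#'
#' Iterates through ranks `k = 1..n-2`: at each step, at most two HSPR moves
#' at rank `k` make the cluster of rank `k` agree with the target tree while
#' clusters below `k` stay fixed. The resulting path certifies connectivity
#' of the treespace and has length at most `2(n-2)`; it is an approximation,
#' not an exact distance.
#' @param from,to `rankedTree` objects on the same leaf set.
#' @return a `treePath` from `from` to `to` (empty when the trees are equal).
#' @export
bottomUpPath <- function(from, to) {
  requireSameLeaves(from, to)
  n <- nLeaves(from)
  cur <- from
  trees <- list(from)
  moves <- list()
  push <- function(mv) {
    cur <<- applyHspr(cur, mv)
    trees[[length(trees) + 1L]] <<- cur
    moves[[length(moves) + 1L]] <<- mv
  }
  stTo <- treeStructure(to$clusters, n)
  for (k in seq_len(max(0L, n - 2L))) {
    target <- sort(stTo$childMask[, k])
    stCur <- treeStructure(cur$clusters, n)
    have <- sort(stCur$childMask[, k])
    if (identical(have, target)) next
    Ri <- target[1L]; Rj <- target[2L]
    attachEdge <- function(m) {
      p <- parentRankOfMask(cur$clusters, m)
      c(as.character(p), maskLabel(cur, m))
    }
    if (Ri %in% have || Rj %in% have) {
      pruneM <- if (Ri %in% have) Ri else Rj
      otherM <- if (Ri %in% have) Rj else Ri
      push(hsprMove(k, maskLabel(cur, pruneM), attachEdge(otherM)))
    } else {
      push(hsprMove(k, maskLabel(cur, have[1L]), attachEdge(Ri)))
      stCur <- treeStructure(cur$clusters, n)
      push(hsprMove(k, maskLabel(cur, Ri), attachEdge(Rj)))
    }
  }
  if (!treeEqual(cur, to)) {
    rsprStop("InvalidMove", "bottom-up construction failed to reach the target")
  }
  treePath(trees, moves)
}

#' Leaf-parent lower bound on the HSPR distance
#'
#' A single HSPR move changes the parents of at most two leaves, so if the
#' parents of `x` leaves have different ranks in the two trees, at least
#' `ceil(x/2)` moves are needed.
#' @param from,to `rankedTree` objects on the same leaf set.
#' @return `list(x = <count of leaves with differing parent rank>,
#'   bound = ceil(x/2))`.
#' @export
leafParentBound <- function(from, to) {
  requireSameLeaves(from, to)
  n <- nLeaves(from)
  pa <- treeStructure(from$clusters, n)$leafParent
  pb <- treeStructure(to$clusters, n)$leafParent
  x <- sum(pa != pb)
  list(x = x, bound = as.integer(ceiling(x / 2)))
}

# --- BFS machinery ---------------------------------------------------------

#' @keywords internal
maskKey <- function(cl) paste(cl, collapse = ",")

#' @keywords internal
rowKeys <- function(M) {
  if (nrow(M) == 0L) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(M)), function(j) M[, j]), list(sep = ",")))
}

#' @keywords internal
neighborMaskRows <- function(cl, n, metric) {
  M <- hsprNeighborMasks(cl, n)
  if (metric == "rspr") M <- rbind(M, rankNeighborMasks(cl))
  M
}

#' @keywords internal
rankOnlyNeighborRows <- function(cl, n) rankNeighborMasks(cl)

# Bidirectional BFS between two mask vectors; neighborFun(cl) returns a
# matrix of neighbour rows.
#' @keywords internal
bfsDistanceMasks <- function(a, b, neighborFun) {
  ka <- maskKey(a); kb <- maskKey(b)
  if (ka == kb) return(0L)
  sideA <- new.env(parent = emptyenv()); assign(ka, 0L, envir = sideA)
  sideB <- new.env(parent = emptyenv()); assign(kb, 0L, envir = sideB)
  frontA <- list(a); frontB <- list(b)
  dA <- 0L; dB <- 0L
  repeat {
    if (length(frontA) == 0L || length(frontB) == 0L) {
      rsprStop("LeafSetMismatch", "trees are not connected")  # cannot happen
    }
    expandA <- length(frontA) <= length(frontB)
    front <- if (expandA) frontA else frontB
    mine <- if (expandA) sideA else sideB
    other <- if (expandA) sideB else sideA
    depth <- (if (expandA) dA else dB) + 1L
    nxt <- list()
    best <- Inf
    for (cl in front) {
      M <- neighborFun(cl)
      keys <- rowKeys(M)
      newRows <- which(!duplicated(keys) & !vapply(keys, exists, TRUE, envir = mine,
                                                  inherits = FALSE))
      for (r in newRows) {
        assign(keys[r], depth, envir = mine)
        if (exists(keys[r], envir = other, inherits = FALSE)) {
          best <- min(best, depth + get(keys[r], envir = other, inherits = FALSE))
        }
        nxt[[length(nxt) + 1L]] <- M[r, ]
      }
    }
    if (is.finite(best)) return(as.integer(best))
    if (expandA) { frontA <- nxt; dA <- depth } else { frontB <- nxt; dB <- depth }
  }
}

#' Exact distance between two ranked trees
#'
#' Breadth-first search over the chosen move graph (bidirectional, expanding
#' the smaller frontier). Exact but exponential in `n`; guarded by
#' `maxLeaves`.
#' @param from,to `rankedTree` objects on the same leaf set.
#' @param metric `"hspr"` or `"rspr"`.
#' @param maxLeaves search guard; trees with more leaves raise
#'   `SearchBudgetExceeded` (raise it explicitly if you know what you are
#'   doing).
#' @return integer distance; 0 iff the trees are identical.
#' @export
treeDistance <- function(from, to, metric = c("hspr", "rspr"), maxLeaves = 8L) {
  metric <- match.arg(metric)
  requireSameLeaves(from, to)
  n <- nLeaves(from)
  if (n > maxLeaves) {
    rsprStop("SearchBudgetExceeded",
             sprintf("BFS guard: %d leaves > maxLeaves = %d", n, maxLeaves))
  }
  bfsDistanceMasks(from$clusters, to$clusters,
                   function(cl) neighborMaskRows(cl, n, metric))
}

#' Minimum number of rank moves between two rankings of one topology
#'
#' BFS restricted to rank moves; defined only for trees with identical
#' unranked topology (otherwise no rank-move path exists).
#' @param from,to `rankedTree` objects with equal unranked topologies.
#' @return integer distance.
#' @export
rankMoveDistance <- function(from, to) {
  requireSameLeaves(from, to)
  if (!topologyEqual(from, to)) {
    rsprStop("TopologyMismatch", "trees do not share their unranked topology")
  }
  n <- nLeaves(from)
  bfsDistanceMasks(from$clusters, to$clusters,
                   function(cl) rankOnlyNeighborRows(cl, n))
}

#' Enumerate every shortest path between two trees
#'
#' Forward BFS records, for each vertex at distance `d` from the source, all
#' predecessors at distance `d-1`; backtracking from the target yields every
#' geodesic. Paths are returned in a deterministic order (lexicographic by
#' their serialized move sequences).
#' @param from,to `rankedTree` objects on the same leaf set.
#' @param metric `"hspr"` or `"rspr"`.
#' @param maxLeaves search guard as in [treeDistance()].
#' @return list of `treePath` objects, all of the same (minimal) length.
#' @export
allShortestPaths <- function(from, to, metric = c("hspr", "rspr"), maxLeaves = 8L) {
  metric <- match.arg(metric)
  requireSameLeaves(from, to)
  n <- nLeaves(from)
  if (n > maxLeaves) {
    rsprStop("SearchBudgetExceeded",
             sprintf("BFS guard: %d leaves > maxLeaves = %d", n, maxLeaves))
  }
  src <- maskKey(from$clusters); dst <- maskKey(to$clusters)
  if (src == dst) {
    return(list(treePath(list(from), list())))
  }
  dist <- new.env(parent = emptyenv())
  preds <- new.env(parent = emptyenv())
  masks <- new.env(parent = emptyenv())
  assign(src, 0L, envir = dist)
  assign(src, from$clusters, envir = masks)
  frontier <- list(from$clusters)
  d <- 0L
  found <- FALSE
  while (!found && length(frontier) > 0L) {
    d <- d + 1L
    nxt <- list()
    for (cl in frontier) {
      k <- maskKey(cl)
      M <- neighborMaskRows(cl, n, metric)
      keys <- rowKeys(M)
      for (r in seq_len(nrow(M))) {
        kk <- keys[r]
        dv <- if (exists(kk, envir = dist, inherits = FALSE)) {
          get(kk, envir = dist, inherits = FALSE)
        } else NA_integer_
        if (is.na(dv)) {
          assign(kk, d, envir = dist)
          assign(kk, M[r, ], envir = masks)
          assign(kk, list(k), envir = preds)
          nxt[[length(nxt) + 1L]] <- M[r, ]
          if (kk == dst) found <- TRUE
        } else if (dv == d) {
          assign(kk, c(get(kk, envir = preds, inherits = FALSE), list(k)),
                 envir = preds)
        }
      }
    }
    frontier <- nxt
  }
  backtrack <- function(key) {
    if (key == src) return(list(list(key)))
    out <- list()
    for (p in unique(unlist(get(key, envir = preds, inherits = FALSE)))) {
      for (tail in backtrack(p)) {
        out[[length(out) + 1L]] <- c(tail, list(key))
      }
    }
    out
  }
  seqs <- backtrack(dst)
  paths <- lapply(seqs, function(s) {
    trees <- lapply(s, function(k) {
      newRankedTree(from$labels, get(k, envir = masks, inherits = FALSE))
    })
    mvs <- lapply(seq_len(length(trees) - 1L), function(i) {
      moveBetween(trees[[i]], trees[[i + 1L]], metric)
    })
    treePath(trees, mvs)
  })
  ord <- order(vapply(paths, function(p) {
    paste(vapply(p$moves, formatMove, ""), collapse = " ")
  }, ""))
  paths[ord]
}

# --- path transformations --------------------------------------------------

#' @keywords internal
moveRank <- function(m) m$rank

#' Swap a rank-decreasing pair of HSPR moves on a path
#'
#' Given consecutive HSPR moves at ranks `k > i` on a path, replaces the
#' intermediate tree so that the rank-`i` move comes first, preserving the
#' endpoints and the length. The intermediate is found by exhaustive search
#' over the rank-`i` neighbours of the left tree; non-existence would
#' falsify the underlying exchange property and raises `NoIntermediateFound`.
#' @param path a `treePath` of HSPR moves.
#' @param index position of the first move of the pair (1-based).
#' @return a `treePath` with the same endpoints and length.
#' @export
swapDecreasingHspr <- function(path, index) {
  if (index < 1L || index + 1L > pathLength(path)) {
    rsprStop("NotDecreasingPair", "index does not address two consecutive moves")
  }
  m1 <- path$moves[[index]]; m2 <- path$moves[[index + 1L]]
  if (!inherits(m1, "hsprMove") || !inherits(m2, "hsprMove") ||
      !(moveRank(m1) > moveRank(m2))) {
    rsprStop("NotDecreasingPair",
             "the addressed moves are not HSPR moves at decreasing ranks")
  }
  k <- moveRank(m1); i <- moveRank(m2)
  T0 <- path$trees[[index]]; T2 <- path$trees[[index + 2L]]
  for (mA in neighborMoves(T0, "hspr")) {
    if (moveRank(mA) != i) next
    mid <- applyHspr(T0, mA)
    for (mB in neighborMoves(mid, "hspr")) {
      if (moveRank(mB) != k) next
      if (treeEqual(applyHspr(mid, mB), T2)) {
        trees <- path$trees; moves <- path$moves
        trees[[index + 1L]] <- mid
        moves[[index]] <- mA; moves[[index + 1L]] <- mB
        return(treePath(trees, moves))
      }
    }
  }
  rsprStop("NoIntermediateFound",
           "no rank-increasing replacement exists for this pair (should be impossible)")
}

#' Sort the HSPR moves of a path into non-decreasing rank order
#'
#' Repeatedly applies [swapDecreasingHspr()] until the ranks of the HSPR
#' moves increase monotonically along the path. Length and endpoints are
#' preserved.
#' @param path a `treePath` of HSPR moves.
#' @return a `treePath`.
#' @export
monotoneRankPath <- function(path) {
  repeat {
    ranks <- vapply(path$moves, moveRank, 0L)
    bad <- which(diff(ranks) < 0L)
    if (length(bad) == 0L) return(path)
    path <- swapDecreasingHspr(path, bad[1L])
  }
}

#' Move all rank moves of an RSPR path to its beginning
#'
#' Any path can be rearranged, without changing its endpoints or length, so
#' that all rank moves come first, followed by HSPR moves only. Each local
#' fix replaces an (HSPR, rank) pair of consecutive moves by either a
#' (rank, HSPR) or an (HSPR, HSPR) pair, found by exhaustive search over
#' single intermediates; non-existence would falsify the underlying exchange
#' property and raises `NoIntermediateFound`.
#' @param path a `treePath` of RSPR moves.
#' @return a `treePath` in which no rank move follows an HSPR move.
#' @export
normalizeRankFirst <- function(path) {
  repeat {
    isRank <- vapply(path$moves, inherits, TRUE, what = "rankMove")
    j <- which(!isRank[-length(isRank)] & isRank[-1L])
    if (length(isRank) < 2L || length(j) == 0L) return(path)
    j <- j[1L]
    T0 <- path$trees[[j]]; T2 <- path$trees[[j + 2L]]
    fixed <- NULL
    candidates <- c(lapply(rankIntervals(T0), function(iv) rankMove(iv[2L])),
                    neighborMoves(T0, "hspr"))
    for (mA in candidates) {
      mid <- applyMove(T0, mA)
      for (mB in neighborMoves(mid, "hspr")) {
        if (treeEqual(applyHspr(mid, mB), T2)) {
          fixed <- list(mA = mA, mid = mid, mB = mB)
          break
        }
      }
      if (!is.null(fixed)) break
    }
    if (is.null(fixed)) {
      rsprStop("NoIntermediateFound",
               "no replacement for an (HSPR, rank) pair (should be impossible)")
    }
    trees <- path$trees; moves <- path$moves
    trees[[j + 1L]] <- fixed$mid
    moves[[j]] <- fixed$mA; moves[[j + 1L]] <- fixed$mB
    path <- treePath(trees, moves)
  }
}

#' Cyclic permutation path of subtree attachments
#'
#' Given `d` pairwise distinct subtrees of `tree`, all of whose roots rank
#' strictly below every one of their parents' ranks, constructs the HSPR
#' path of length `d` that cyclically permutes their attachment positions
#' (subtree `j` ends up where subtree `j+1` was, and subtree `d` where
#' subtree `1` was). This witnesses that the endpoint is at distance at
#' most `d`.
#' @param tree a `rankedTree`.
#' @param cycle character vector of `d >= 2` node labels (leaf names or
#'   ranks) identifying the subtree roots, in cycle order.
#' @return a `treePath` of length `d` starting at `tree`.
#' @export
cyclePath <- function(tree, cycle) {
  d <- length(cycle)
  if (d < 2L) rsprStop("PreconditionViolated", "a cycle needs at least two subtrees")
  if (anyDuplicated(cycle)) {
    rsprStop("PreconditionViolated", "cycle contains two identical subtrees")
  }
  n <- nLeaves(tree)
  masks <- vapply(cycle, function(lab) labelMaskOf(tree, lab), 0L)
  ranks <- vapply(cycle, function(lab) labelRankOf(tree, lab), 0L)
  parents <- vapply(masks, function(m) parentRankOfMask(tree$clusters, m), 0L)
  if (anyNA(parents)) rsprStop("PreconditionViolated", "the root cannot be in the cycle")
  if (max(ranks) >= min(parents)) {
    rsprStop("PreconditionViolated",
             "every subtree root must rank below every attachment rank")
  }
  rot <- which.min(parents)
  ord <- c(rot:d, seq_len(rot - 1L))
  masks <- masks[ord]
  k <- parents[rot]
  st <- treeStructure(tree$clusters, n)
  sibling <- st$childMask[st$childMask[, k] != masks[1L], k][1L]
  cur <- tree
  trees <- list(tree); moves <- list()
  push <- function(pruneM, attachM) {
    p <- parentRankOfMask(cur$clusters, attachM)
    mv <- hsprMove(k, maskLabel(cur, pruneM), c(as.character(p), maskLabel(cur, attachM)))
    cur <<- applyHspr(cur, mv)
    trees[[length(trees) + 1L]] <<- cur
    moves[[length(moves) + 1L]] <<- mv
  }
  res <- tryCatch({
    for (j in seq_len(d - 1L)) push(masks[j], masks[j + 1L])
    push(masks[d], sibling)
    treePath(trees, moves)
  }, rankedSPR_error = function(e) e)
  if (inherits(res, "treePath")) return(res)
  rsprStop("PreconditionViolated",
           paste0("cycle does not satisfy the construction's preconditions: ",
                  conditionMessage(res)))
}
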