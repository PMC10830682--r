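# Whole treespaces at small n: graphs, diameters, exhaustive audits.
#
# The vertex set (all ranked trees on n leaves, n!(n-1)!/2^(n-1) of them)
# is enumerated once into a mask matrix; adjacency is precomputed into
# index lists before any eccentricity sweep. Eccentricity is invariant
# under leaf relabelling, so the diameter needs one BFS per tree shape
# (leaf-relabelling orbit) only, which is what makes n = 7 (56,700 trees,
# ~1.7M directed HSPR edges) tractable.

#' Build the treespace graph on n leaves
#'
#' @param n number of leaves (2..7 for HSPR; RSPR defaults to a budget of 6).
#' @param metric `"hspr"` or `"rspr"`.
#' @param leaves leaf labels, default `l1..ln`.
#' @param maxLeaves construction budget guard; exceeding it raises
#'   `BudgetExceeded`.
#' @return an object of class `treespace`: vertex mask matrix, key index and
#'   adjacency lists. Vertex `i` corresponds to `spaceTree(ts, i)`.
#' @export
buildTreespace <- function(n, metric = c("hspr", "rspr"),
                           leaves = defaultLeaves(n),
                           maxLeaves = if (match.arg(metric) == "hspr") 7L else 6L) {
  metric <- match.arg(metric)
  if (n < 2L) rsprStop("EmptyInput", "need n >= 2")
  if (n > maxLeaves) {
    rsprStop("BudgetExceeded",
             sprintf("treespace on %d leaves exceeds the budget (maxLeaves = %d)",
                     n, maxLeaves))
  }
  labels <- leaves[order(leaves)]
  M <- enumTreeMasks(n)
  N <- nrow(M)
  keys <- rowKeys(M)
  index <- new.env(parent = emptyenv(), size = N)
  list2env(stats::setNames(as.list(seq_len(N)), keys), envir = index)
  adj <- vector("list", N)
  for (t in seq_len(N)) {
    nb <- neighborMaskRows(M[t, ], n, metric)
    ids <- unlist(mget(rowKeys(nb), envir = index), use.names = FALSE)
    adj[[t]] <- if (is.null(ids)) integer(0) else ids
  }
  structure(list(n = n, metric = metric, labels = labels,
                 masks = M, keys = keys, adj = adj, index = index),
            class = "treespace")
}

#' @export
print.treespace <- function(x, ...) {
  cat(sprintf("%s treespace on %d leaves: %d trees, %d directed edges\n",
              toupper(x$metric), x$n, nrow(x$masks), sum(lengths(x$adj))))
  invisible(x)
}

#' Tree at a treespace vertex
#' @param ts a `treespace`.
#' @param i vertex index.
#' @return a `rankedTree`.
#' @export
spaceTree <- function(ts, i) newRankedTree(ts$labels, ts$masks[i, ])

#' Vertex index of a tree in a treespace
#' @param ts a `treespace`.
#' @param tree a `rankedTree` on the same leaf set.
#' @return integer index.
#' @export
spaceIndex <- function(ts, tree) {
  if (!identical(tree$labels, ts$labels)) {
    rsprStop("LeafSetMismatch", "tree is not on the treespace's leaf set")
  }
  k <- maskKey(tree$clusters)
  if (!exists(k, envir = ts$index, inherits = FALSE)) {
    rsprStop("UnknownLeaf", "tree not found in the treespace")  # cannot happen for valid trees
  }
  get(k, envir = ts$index, inherits = FALSE)
}

#' Single-source BFS distances over a treespace
#' @param ts a `treespace`.
#' @param from source vertex index.
#' @return integer vector of distances (`NA` would mean unreachable).
#' @export
spaceBfs <- function(ts, from) {
  N <- nrow(ts$masks)
  dist <- rep(NA_integer_, N)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(unlist(ts$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' All-pairs distance matrix of a treespace
#'
#' One BFS per vertex; intended for n <= 5.
#' @param ts a `treespace`.
#' @return integer matrix of distances.
#' @export
spaceDistances <- function(ts) {
  N <- nrow(ts$masks)
  vapply(seq_len(N), function(i) spaceBfs(ts, i), integer(N))
}

#' Is the treespace connected?
#' @param ts a `treespace`.
#' @return logical.
#' @export
spaceConnected <- function(ts) !anyNA(spaceBfs(ts, 1L))

# Canonical shape key of a mask row: leaves renamed by order of first
# appearance in the rank-ordered cluster list. Two trees get the same key
# iff one is a leaf relabelling of the other (leaves first appearing
# together do so as an exchangeable cherry, so the within-cluster order is
# immaterial).
#' @keywords internal
shapeKeyRow <- function(row, n, bitvals = bitwShiftL(1L, 0:(n - 1L))) {
  mapping <- integer(n)
  nxt <- 0L
  for (m in row) {
    for (b in which(bitwAnd(m, bitvals) > 0L)) {
      if (mapping[b] == 0L) {
        nxt <- nxt + 1L
        mapping[b] <- nxt
      }
    }
  }
  paste(vapply(row, function(m) {
    sum(bitvals[mapping[which(bitwAnd(m, bitvals) > 0L)]])
  }, 0), collapse = ",")
}

#' Leaf-relabelling orbit representatives of a treespace
#' @param ts a `treespace`.
#' @return integer vector of vertex indices, one per tree shape.
#' @export
shapeRepresentatives <- function(ts) {
  n <- ts$n
  bitvals <- bitwShiftL(1L, 0:(n - 1L))
  keys <- vapply(seq_len(nrow(ts$masks)), function(i) {
    shapeKeyRow(ts$masks[i, ], n, bitvals)
  }, "")
  which(!duplicated(keys))
}

#' Diameter of a treespace
#'
#' Maximum eccentricity, computed with one BFS per leaf-relabelling orbit
#' representative (eccentricity is invariant under leaf permutations, which
#' are graph automorphisms of both HSPR and RSPR space).
#' @param x a `treespace`, or a leaf count `n`.
#' @param metric move set, used when `x` is a leaf count.
#' @param maxLeaves budget guard forwarded to [buildTreespace()].
#' @return integer diameter.
#' @export
treespaceDiameter <- function(x, metric = c("hspr", "rspr"),
                              maxLeaves = if (match.arg(metric) == "hspr") 7L else 6L) {
  metric <- match.arg(metric)
  ts <- if (inherits(x, "treespace")) x else buildTreespace(x, metric, maxLeaves = maxLeaves)
  reps <- shapeRepresentatives(ts)
  ecc <- vapply(reps, function(r) {
    d <- spaceBfs(ts, r)
    if (anyNA(d)) rsprStop("BudgetExceeded", "treespace is not connected")
    max(d)
  }, integer(1L))
  max(ecc)
}

# --- audit machinery -------------------------------------------------------

#' @keywords internal
newAuditReport <- function(property, n, metric, checked, witnesses = list(),
                           violations = list()) {
  structure(list(property = property, n = n, metric = metric,
                 checked = checked, violations = violations,
                 witnesses = witnesses),
            class = "auditReport")
}

#' @export
print.auditReport <- function(x, ...) {
  cat(sprintf("audit '%s' (n = %d, %s): %d instances checked, %d violations\n",
              x$property, x$n, toupper(x$metric), x$checked,
              length(x$violations)))
  if (length(x$witnesses) > 0L) {
    cat(sprintf("  %d witness(es) recorded\n", length(x$witnesses)))
  }
  invisible(x)
}

#' Number of audit violations
#' @param report an `auditReport`.
#' @return integer.
#' @export
auditViolations <- function(report) length(report$violations)

# first rank at which two mask rows differ = rank of the move between
# adjacent trees (HSPR at rank i changes the rank-i cluster and only
# clusters above it; a rank move at r changes exactly ranks r, r+1)
#' @keywords internal
firstDiffRank <- function(M, u, v) which(M[u, ] != M[v, ])[1L]

#' Exhaustive audit of a structural property of the treespace
#'
#' Checks one of the package's machine-checkable treespace properties over
#' every applicable pair (or geodesic) of the enumerated treespace on `n`
#' leaves, and reports the number of instances checked and any violations.
#'
#' Available properties:
#' * `"neighbourhood_size"`: every vertex has `(n-1)(n-2)` HSPR neighbours,
#'   plus its rank-interval count under RSPR.
#' * `"connected"`: the move graph has a single component.
#' * `"cherry_preservation"`: for trees sharing their rank-one cherry, every
#'   vertex on every HSPR geodesic carries that cherry.
#' * `"cherry_deletion"`: deleting a shared rank-one cherry leaf leaves the
#'   HSPR distance unchanged.
#' * `"cluster_prefix"`: clusters shared at every rank below some `i` are
#'   carried by every vertex of every HSPR geodesic.
#' * `"monotone_ranks"`: every pair admits an HSPR geodesic whose move ranks
#'   are non-decreasing.
#' * `"no_subtree_repeat"`: on geodesics consisting of HSPR moves at one
#'   fixed rank, no subtree moves twice.
#' * `"no_weak_cluster"`: the 5-leaf witness pair sharing `{l4,l5}` has no
#'   geodesic (in the chosen metric) preserving the shared cluster.
#' * `"caterpillar_metric_equality"`: caterpillar pairs have equal HSPR and
#'   RSPR distance.
#' * `"rank_first_normalization"`: every RSPR geodesic normalizes to rank
#'   moves first with unchanged endpoints and length.
#' * `"ranking_equalizer"`: every pair of unranked topologies admits
#'   rankings whose RSPR and HSPR distances coincide.
#' * `"leaf_addition_collapse"`: the rotated caterpillar pair on `n` leaves
#'   has distance at least `ceil((n-1)/2)` while a leaf addition (above the
#'   root / as rank-one cherry) brings the distance down to one.
#'
#' @param property property id (see above).
#' @param n number of leaves audited.
#' @param metric `"hspr"` or `"rspr"` (some audits fix their own metric).
#' @return an `auditReport`; `auditViolations()` is 0 whenever the audited
#'   statement holds on this treespace.
#' @export
auditTreespace <- function(property, n, metric = c("hspr", "rspr")) {
  metric <- match.arg(metric)
  switch(property,
    neighbourhood_size = auditNeighbourhoodSize(n, metric),
    connected = auditConnected(n, metric),
    cherry_preservation = auditCherryPreservation(n),
    cherry_deletion = auditCherryDeletion(n),
    cluster_prefix = auditClusterPrefix(n),
    monotone_ranks = auditMonotoneRanks(n),
    no_subtree_repeat = auditNoSubtreeRepeat(n),
    no_weak_cluster = auditNoWeakCluster(metric),
    caterpillar_metric_equality = auditCaterpillarEquality(n),
    rank_first_normalization = auditRankFirstNormalization(n),
    ranking_equalizer = auditRankingEqualizer(n),
    leaf_addition_collapse = auditLeafAdditionCollapse(n),
    rsprStop("UnknownProperty", paste0("unknown audit property: ", property))
  )
}

#' @keywords internal
auditNeighbourhoodSize <- function(n, metric) {
  ts <- buildTreespace(n, metric)
  deg <- lengths(ts$adj)
  expect <- (n - 1L) * (n - 2L)
  if (metric == "rspr") {
    k <- vapply(seq_len(nrow(ts$masks)), function(i) {
      cl <- ts$masks[i, ]
      sum(bitwAnd(cl[-length(cl)], cl[-1L]) != cl[-length(cl)])
    }, integer(1L))
    expect <- expect + k
  }
  bad <- which(deg != expect)
  newAuditReport("neighbourhood_size", n, metric, length(deg),
                 violations = as.list(bad))
}

#' @keywords internal
auditConnected <- function(n, metric) {
  ts <- buildTreespace(n, metric)
  ok <- spaceConnected(ts)
  newAuditReport("connected", n, metric, nrow(ts$masks),
                 violations = if (ok) list() else list("disconnected"))
}

#' @keywords internal
auditCherryPreservation <- function(n) {
  ts <- buildTreespace(n, "hspr")
  D <- spaceDistances(ts)
  first <- ts$masks[, 1L]
  viol <- list()
  checked <- 0L
  for (cherry in unique(first)) {
    grp <- which(first == cherry)
    for (a in seq_along(grp)) {
      for (b in seq_along(grp)) {
        if (a >= b) next
        s <- grp[a]; t <- grp[b]
        checked <- checked + 1L
        onGeo <- which(D[s, ] + D[, t] == D[s, t])
        if (any(first[onGeo] != cherry)) {
          viol[[length(viol) + 1L]] <- c(s, t)
        }
      }
    }
  }
  newAuditReport("cherry_preservation", n, "hspr", checked, violations = viol)
}

#' @keywords internal
auditCherryDeletion <- function(n) {
  ts <- buildTreespace(n, "hspr")
  D <- spaceDistances(ts)
  first <- ts$masks[, 1L]
  viol <- list()
  checked <- 0L
  smallDist <- new.env(parent = emptyenv())
  for (cherry in unique(first)) {
    grp <- which(first == cherry)
    # delete the lexicographically larger leaf of the shared cherry
    leaf <- sort(maskMembers(cherry, ts$labels))[2L]
    reduced <- lapply(grp, function(i) deleteCherryLeaf(spaceTree(ts, i), leaf))
    for (a in seq_along(grp)) {
      for (b in seq_along(grp)) {
        if (a >= b) next
        checked <- checked + 1L
        dSmall <- treeDistance(reduced[[a]], reduced[[b]], "hspr")
        if (dSmall != D[grp[a], grp[b]]) {
          viol[[length(viol) + 1L]] <- c(grp[a], grp[b])
        }
      }
    }
  }
  newAuditReport("cherry_deletion", n, "hspr", checked, violations = viol)
}

#' @keywords internal
auditClusterPrefix <- function(n) {
  ts <- buildTreespace(n, "hspr")
  D <- spaceDistances(ts)
  N <- nrow(ts$masks)
  viol <- list()
  checked <- 0L
  for (s in seq_len(N)) {
    for (t in seq_len(N)) {
      if (s >= t) next
      shared <- ts$masks[s, ] == ts$masks[t, ]
      pre <- which(!shared)[1L] - 1L   # clusters 1..pre agree
      if (is.na(pre) || pre < 1L) next
      checked <- checked + 1L
      onGeo <- which(D[s, ] + D[, t] == D[s, t])
      agree <- ts$masks[onGeo, seq_len(pre), drop = FALSE] ==
        matrix(ts$masks[s, seq_len(pre)], length(onGeo), pre, byrow = TRUE)
      if (!all(agree)) viol[[length(viol) + 1L]] <- c(s, t)
    }
  }
  newAuditReport("cluster_prefix", n, "hspr", checked, violations = viol)
}

#' @keywords internal
auditMonotoneRanks <- function(n) {
  ts <- buildTreespace(n, "hspr")
  N <- nrow(ts$masks)
  M <- ts$masks
  viol <- list()
  for (t in seq_len(N)) {
    dist <- spaceBfs(ts, t)
    ord <- order(dist)
    best <- rep(-Inf, N)
    best[t] <- Inf
    for (v in ord) {
      if (dist[v] == 0L) next
      for (w in ts$adj[[v]]) {
        if (dist[w] != dist[v] - 1L) next
        r <- firstDiffRank(M, v, w)
        if (r <= best[w] && r > best[v]) best[v] <- r
      }
    }
    bad <- which(!is.finite(best) & best < 0)
    for (v in bad) viol[[length(viol) + 1L]] <- c(v, t)
  }
  newAuditReport("monotone_ranks", n, "hspr", N * (N - 1L), violations = viol)
}

#' @keywords internal
auditNoSubtreeRepeat <- function(n) {
  ts <- buildTreespace(n, "hspr")
  D <- spaceDistances(ts)
  N <- nrow(ts$masks)
  viol <- list()
  checked <- 0L
  for (k in seq_len(n - 2L)) {
    adjK <- lapply(seq_len(N), function(i) {
      st <- treeStructure(ts$masks[i, ], n)
      nb <- hsprNeighborRowsAtRank(ts$masks[i, ], n, k, st)
      if (nrow(nb) == 0L) integer(0) else
        unlist(mget(rowKeys(nb), envir = ts$index), use.names = FALSE)
    })
    # geodesics within the rank-k subgraph that are also global geodesics
    for (s in seq_len(N)) {
      dk <- subgraphBfs(adjK, s)
      for (t in which(!is.na(dk) & dk > 0L)) {
        if (dk[t] != D[s, t]) next
        checked <- checked + 1L
        for (pth in subgraphGeodesics(adjK, dk, s, t)) {
          moved <- vapply(seq_len(length(pth) - 1L), function(j) {
            movedSubtreeMask(ts$masks[pth[j], ], ts$masks[pth[j + 1L], ], n, k)
          }, 0L)
          if (anyDuplicated(moved)) viol[[length(viol) + 1L]] <- pth
        }
      }
    }
  }
  newAuditReport("no_subtree_repeat", n, "hspr", checked, violations = viol)
}

#' @keywords internal
hsprNeighborRowsAtRank <- function(cl, n, i, st = treeStructure(cl, n)) {
  nodeMask <- c(bitwShiftL(1L, 0:(n - 1L)), cl)
  nodeRank <- c(integer(n), seq_len(n - 1L))
  parentRk <- c(st$leafParent, st$internalParent)
  cover <- which(nodeRank < i & !is.na(parentRk) & parentRk > i)
  if (length(cover) == 0L) return(matrix(0L, 0L, n - 1L))
  rows <- list()
  for (B in st$childMask[, i]) {
    for (C in nodeMask[cover]) {
      rows[[length(rows) + 1L]] <- applyHsprMask(cl, i, B, C)
    }
  }
  do.call(rbind, rows)
}

#' @keywords internal
subgraphBfs <- function(adj, from) {
  N <- length(adj)
  dist <- rep(NA_integer_, N)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' @keywords internal
subgraphGeodesics <- function(adj, dist, s, t) {
  rec <- function(v) {
    if (v == s) return(list(s))
    out <- list()
    for (w in adj[[v]]) {
      if (!is.na(dist[w]) && dist[w] == dist[v] - 1L) {
        for (tail in rec(w)) out[[length(out) + 1L]] <- c(tail, v)
      }
    }
    out
  }
  rec(t)
}

# the subtree moved between two trees adjacent by an HSPR move at rank k:
# the common child block of the rank-k nodes
#' @keywords internal
movedSubtreeMask <- function(clA, clB, n, k) {
  a <- treeStructure(clA, n)$childMask[, k]
  b <- treeStructure(clB, n)$childMask[, k]
  common <- intersect(a, b)
  if (length(common) != 1L) {
    rsprStop("InvalidMove", "trees are not related by an HSPR move at this rank")
  }
  common
}

#' @keywords internal
auditNoWeakCluster <- function(metric) {
  T7 <- rankedTree(list(c("l1", "l2"), c("l1", "l2", "l3"), c("l4", "l5")))
  R7 <- rankedTree(list(c("l4", "l5"), c("l2", "l3"), c("l1", "l4", "l5")))
  shared <- maskOf(c("l4", "l5"), T7$labels)
  paths <- allShortestPaths(T7, R7, metric)
  preserving <- Filter(function(p) {
    all(vapply(p$trees, function(tr) shared %in% tr$clusters, TRUE))
  }, paths)
  newAuditReport("no_weak_cluster", 5L, metric, length(paths),
                 violations = preserving,
                 witnesses = list(list(pair = list(T7, R7),
                                       geodesics = length(paths))))
}

#' @keywords internal
auditCaterpillarEquality <- function(n) {
  tsH <- buildTreespace(n, "hspr")
  tsR <- buildTreespace(n, "rspr")
  cat.idx <- which(vapply(seq_len(nrow(tsH$masks)), function(i) {
    cl <- tsH$masks[i, ]
    all(bitwAnd(cl[-length(cl)], cl[-1L]) == cl[-length(cl)])
  }, TRUE))
  viol <- list()
  checked <- 0L
  for (a in cat.idx) {
    dH <- spaceBfs(tsH, a)
    dR <- spaceBfs(tsR, a)
    for (b in cat.idx) {
      if (a >= b) next
      checked <- checked + 1L
      if (dH[b] != dR[b]) viol[[length(viol) + 1L]] <- c(a, b)
    }
  }
  newAuditReport("caterpillar_metric_equality", n, "rspr", checked,
                 violations = viol)
}

#' @keywords internal
auditRankFirstNormalization <- function(n) {
  trees <- enumerateTrees(n)
  viol <- list()
  checked <- 0L
  for (a in seq_along(trees)) {
    for (b in seq_along(trees)) {
      if (a >= b) next
      for (p in allShortestPaths(trees[[a]], trees[[b]], "rspr")) {
        checked <- checked + 1L
        q <- normalizeRankFirst(p)
        isRank <- vapply(q$moves, inherits, TRUE, what = "rankMove")
        ok <- pathLength(q) == pathLength(p) &&
          treeEqual(q$trees[[1L]], p$trees[[1L]]) &&
          treeEqual(q$trees[[length(q$trees)]], p$trees[[length(p$trees)]]) &&
          (!any(isRank) || all(which(isRank) == seq_len(sum(isRank))))
        if (!ok) viol[[length(viol) + 1L]] <- c(a, b)
      }
    }
  }
  newAuditReport("rank_first_normalization", n, "rspr", checked,
                 violations = viol)
}

#' @keywords internal
auditRankingEqualizer <- function(n) {
  tsH <- buildTreespace(n, "hspr")
  tsR <- buildTreespace(n, "rspr")
  DH <- spaceDistances(tsH)
  DR <- spaceDistances(tsR)
  topoKey <- vapply(seq_len(nrow(tsH$masks)), function(i) {
    paste(sort(tsH$masks[i, ]), collapse = ",")
  }, "")
  groups <- split(seq_along(topoKey), topoKey)
  viol <- list()
  checked <- 0L
  for (ga in groups) {
    for (gb in groups) {
      checked <- checked + 1L
      ok <- any(DR[ga, gb, drop = FALSE] == DH[ga, gb, drop = FALSE])
      if (!ok) viol[[length(viol) + 1L]] <- c(ga[1L], gb[1L])
    }
  }
  newAuditReport("ranking_equalizer", n, "rspr", checked, violations = viol)
}

#' @keywords internal
auditLeafAdditionCollapse <- function(n) {
  base <- lemmaCaterpillarPair(n)
  Tp <- addLeaf(base$T, paste0("l", n + 1L), "above_root")
  Rp <- addLeaf(base$R, paste0("l", n + 1L), "rank_one_cherry", sibling = "l1")
  dBig <- treeDistance(base$T, base$R, "hspr")
  dSmall <- treeDistance(Tp, Rp, "hspr", maxLeaves = n + 1L)
  viol <- list()
  if (dBig < ceiling((n - 1L) / 2)) viol[[length(viol) + 1L]] <- "lower bound"
  if (dSmall != 1L) viol[[length(viol) + 1L]] <- "added-leaf distance"
  newAuditReport("leaf_addition_collapse", n, "hspr", 2L, violations = viol,
                 witnesses = list(list(dBig = dBig, dSmall = dSmall)))
}

#' The rotated caterpillar pair on n leaves
#'
#' `T` is the caterpillar `(l1, l2, ..., ln)` and `R` the caterpillar
#' `(l2, l3, ..., ln)` with `l1` attached below the root; the parents of all
#' leaves but `l2` differ in rank, forcing distance at least
#' `ceil((n-1)/2)` in both metrics.
#' @param n number of leaves (>= 4).
#' @return `list(T = <rankedTree>, R = <rankedTree>)`.
#' @export
lemmaCaterpillarPair <- function(n) {
  leaves <- defaultLeaves(n)
  Tc <- caterpillarTree(leaves)
  Rc <- rankedTree(c(lapply(seq_len(n - 2L), function(i) leaves[2:(i + 2L)]),
                     list(leaves)),
                   leaves = leaves)
  list(T = Tc, R = Rc)
}

# --- rooted (unranked) SPR one-neighbourhood -------------------------------

#' Are two unranked topologies one rooted SPR move apart?
#'
#' Enumerates every prune/regraft placement on the first topology (any
#' non-root subtree pruned, regrafted on any edge of the remainder or above
#' its root) and tests whether the second topology is produced. Distance 0
#' (identical topologies) returns `FALSE`.
#' @param a,b `unrankedTopology` (or `rankedTree`) objects on the same leaf
#'   set.
#' @return logical.
#' @export
isOneSpr <- function(a, b) {
  a <- unrankedTopology(a); b <- unrankedTopology(b)
  if (!identical(a$labels, b$labels)) {
    rsprStop("LeafSetMismatch", "topologies have different leaf sets")
  }
  if (topologyEqual(a, b)) return(FALSE)
  n <- length(a$labels)
  full <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  target <- sort(b$clusters)
  S <- a$clusters                       # internal clusters incl. root
  pruneCands <- c(bitwShiftL(1L, seq_len(n) - 1L), setdiff(S, full))
  for (B in pruneCands) {
    inside <- S[bitwAnd(S, B) == S]     # travel with the subtree
    anc <- S[bitwAnd(S, B) == B & S != B]
    disj <- S[bitwAnd(S, B) == 0L]
    baseCl <- unique(c(disj, bitwAnd(anc, bitwNot(B))))
    baseCl <- baseCl[popcount(baseCl) >= 2L]       # suppression may leave a leaf
    baseRoot <- bitwAnd(full, bitwNot(B))
    baseNodes <- c(setdiff(baseCl, baseRoot),
                   bitwShiftL(1L, which(bitwAnd(baseRoot,
                                                bitwShiftL(1L, seq_len(n) - 1L)) > 0L) - 1L))
    for (D in baseNodes) {              # regraft on the edge above node D
      newCl <- sort(unique(c(inside,
                             bitwOr(D, B),
                             ifelse(bitwAnd(baseCl, D) == D & baseCl != D,
                                    bitwOr(baseCl, B), baseCl))))
      if (identical(as.integer(newCl), as.integer(target))) return(TRUE)
    }
    # regraft above the root of the remainder
    newCl <- sort(unique(c(inside, baseCl, full)))
    if (identical(as.integer(newCl), as.integer(target))) return(TRUE)
  }
  FALSE
}
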