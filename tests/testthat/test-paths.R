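test_that("tree paths validate replay on construction", {
  T5 <- counterT()
  m <- hsprMove(1, "l1", c("3", "l5"))
  mid <- applyHspr(T5, m)
  p <- treePath(list(T5, mid), list(m))
  expect_equal(pathLength(p), 1L)
  expect_error(treePath(list(T5, T5), list(m)), class = "InvalidMove")
  expect_error(treePath(list(T5), list(m)), class = "InvalidMove")
})

test_that("the bottom-up path reaches the target within 2(n-2) moves", {
  T5 <- counterT(); R5 <- counterR()
  expect_equal(pathLength(bottomUpPath(T5, T5)), 0L)

  p <- bottomUpPath(T5, R5)
  expect_true(treeEqual(p$trees[[length(p$trees)]], R5))
  expect_lte(pathLength(p), 6L)

  set.seed(21)
  for (rep in 1:200) {
    n <- sample(4:8, 1L)
    a <- randomRankedTree(n); b <- randomRankedTree(n)
    q <- bottomUpPath(a, b)
    expect_true(treeEqual(q$trees[[1L]], a))
    expect_true(treeEqual(q$trees[[length(q$trees)]], b))
    expect_lte(pathLength(q), 2L * (n - 2L))
    if (pathLength(q) == 0L) expect_true(treeEqual(a, b))
  }
  expect_error(bottomUpPath(T5, randomRankedTree(4)), class = "LeafSetMismatch")
})

test_that("the bottom-up path is an approximation, not an exact distance", {
  # some 5-leaf pair must be over-estimated
  trees <- enumerateTrees(5)
  set.seed(22)
  found <- FALSE
  for (rep in seq_len(500)) {
    a <- trees[[sample.int(length(trees), 1L)]]
    b <- trees[[sample.int(length(trees), 1L)]]
    if (pathLength(bottomUpPath(a, b)) > treeDistance(a, b, "hspr")) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the leaf-parent count lower-bounds the HSPR distance", {
  T5 <- counterT()
  moved <- applyHspr(T5, hsprMove(1, "l1", c("3", "l5")))
  lp <- leafParentBound(T5, moved)
  expect_equal(lp$x, 2L)
  expect_equal(lp$bound, 1L)

  for (n in 5:7) {
    pair <- shiftedCaterpillarPair(n)
    lp <- leafParentBound(pair$T, pair$R)
    expect_equal(lp$x, n)
    expect_equal(lp$bound, as.integer(ceiling(n / 2)))
  }
  expect_equal(leafParentBound(T5, T5), list(x = 0L, bound = 0L))

  # exhaustive n=4, sampled n=5: bound never exceeds the true distance
  D4 <- spaceDistances(buildTreespace(4, "hspr"))
  t4 <- enumerateTrees(4)
  for (a in seq_along(t4)) {
    for (b in seq_along(t4)) {
      expect_lte(leafParentBound(t4[[a]], t4[[b]])$bound, D4[a, b])
    }
  }
  set.seed(23)
  t5 <- enumerateTrees(5)
  for (rep in 1:100) {
    ab <- sample.int(length(t5), 2L)
    expect_lte(leafParentBound(t5[[ab[1L]]], t5[[ab[2L]]])$bound,
               treeDistance(t5[[ab[1L]]], t5[[ab[2L]]], "hspr"))
  }
})

test_that("BFS distances are exact, symmetric and metric-like", {
  expect_equal(treeDistance(counterT(), counterR(), "hspr"), 2L)
  expect_equal(treeDistance(counterT(), counterT(), "rspr"), 0L)
  cp <- collapsedPair(6)
  expect_equal(treeDistance(cp$T, cp$R, "hspr"), 1L)

  DH <- spaceDistances(buildTreespace(4, "hspr"))
  DR <- spaceDistances(buildTreespace(4, "rspr"))
  expect_true(all(DR <= DH))
  expect_true(all(DH == t(DH)))
  expect_true(all(diag(DH) == 0L) && all(DH[upper.tri(DH)] > 0L))
  # triangle inequality over all 18^3 triples
  N <- nrow(DH)
  for (k in seq_len(N)) {
    expect_true(all(DH <= outer(DH[, k], DH[k, ], `+`)))
    expect_true(all(DR <= outer(DR[, k], DR[k, ], `+`)))
  }
  expect_error(treeDistance(randomRankedTree(9, seed = 1),
                            randomRankedTree(9, seed = 2)),
               class = "SearchBudgetExceeded")
})

test_that("shortest-path enumeration returns every geodesic in stable order", {
  T5 <- counterT()
  same <- allShortestPaths(T5, T5, "hspr")
  expect_length(same, 1L)
  expect_equal(pathLength(same[[1L]]), 0L)

  nb <- applyHspr(T5, hsprMove(1, "l1", c("3", "l5")))
  one <- allShortestPaths(T5, nb, "hspr")
  expect_length(one, 1L)
  expect_equal(pathLength(one[[1L]]), 1L)

  paths <- allShortestPaths(T5, counterR(), "hspr")
  expect_true(all(vapply(paths, pathLength, 0L) == 2L))
  # geodesic count agrees with a direct two-step enumeration
  mid <- Filter(function(nb) treeDistance(nb, counterR(), "hspr") == 1L,
                treeNeighbors(T5, "hspr"))
  expect_length(paths, length(mid))

  shared <- c("l4", "l5")
  hasCluster <- function(tr) {
    any(vapply(clusterList(tr), function(cc) setequal(cc, shared), TRUE))
  }
  for (metric in c("hspr", "rspr")) {
    for (p in allShortestPaths(counterT(), counterR(), metric)) {
      expect_false(all(vapply(p$trees, hasCluster, TRUE)))
    }
  }
})

test_that("rank-move distance works within a topology and rejects others", {
  Rp <- parseClusterList("[{l4,l5},{l1,l2},{l1,l2,l3}]")
  expect_equal(rankMoveDistance(counterT(), Rp), 2L)
  expect_equal(rankMoveDistance(fig3Tree(), fig3Tree()), 0L)
  expect_error(rankMoveDistance(counterT(), counterR()),
               class = "TopologyMismatch")
})

test_that("decreasing HSPR move pairs can always be swapped in place", {
  set.seed(24)
  swapped <- 0L
  for (rep in 1:30) {
    a <- randomRankedTree(5); b <- randomRankedTree(5)
    if (treeEqual(a, b)) next
    for (p in utils::head(allShortestPaths(a, b, "hspr"), 3L)) {
      ranks <- vapply(p$moves, function(m) m$rank, 0L)
      idx <- which(diff(ranks) < 0L)
      for (i in idx) {
        q <- swapDecreasingHspr(p, i)
        expect_equal(pathLength(q), pathLength(p))
        expect_true(treeEqual(q$trees[[1L]], p$trees[[1L]]))
        expect_true(treeEqual(q$trees[[length(q$trees)]],
                              p$trees[[length(p$trees)]]))
        expect_lte(q$moves[[i]]$rank, q$moves[[i + 1L]]$rank)
        swapped <- swapped + 1L
      }
    }
  }
  expect_gt(swapped, 0L)

  # an already increasing pair is rejected
  T5 <- counterT()
  m1 <- hsprMove(1, "l1", c("3", "l5"))
  mid <- applyHspr(T5, m1)
  m2 <- neighborMoves(mid, "hspr")[[which(vapply(neighborMoves(mid, "hspr"),
                                                 function(m) m$rank, 0L) == 2L)[1L]]]
  p <- treePath(list(T5, mid, applyHspr(mid, m2)), list(m1, m2))
  expect_error(swapDecreasingHspr(p, 1L), class = "NotDecreasingPair")
})

test_that("repeated swapping yields monotone move ranks at equal length", {
  set.seed(25)
  for (rep in 1:20) {
    a <- randomRankedTree(5); b <- randomRankedTree(5)
    p <- allShortestPaths(a, b, "hspr")[[1L]]
    q <- monotoneRankPath(p)
    ranks <- vapply(q$moves, function(m) m$rank, 0L)
    expect_true(all(diff(ranks) >= 0L))
    expect_equal(pathLength(q), pathLength(p))
    expect_true(treeEqual(q$trees[[length(q$trees)]], b))
  }
})

test_that("rank moves can be pushed to the front of any RSPR path", {
  # already-normalized path is unchanged
  T5 <- fig3Tree()
  m <- rankMove(1)
  p <- treePath(list(T5, applyRankMove(T5, m)), list(m))
  expect_identical(normalizeRankFirst(p), p)

  # constructed HSPR-then-rank path on 5 leaves gets fixed
  set.seed(26)
  built <- 0L
  while (built < 25L) {
    a <- randomRankedTree(5)
    ms <- neighborMoves(a, "hspr")
    mv1 <- ms[[sample.int(length(ms), 1L)]]
    mid <- applyHspr(a, mv1)
    ivs <- rankIntervals(mid)
    if (length(ivs) == 0L) next
    m2 <- rankMove(ivs[[sample.int(length(ivs), 1L)]][2L])
    pth <- treePath(list(a, mid, applyRankMove(mid, m2)), list(mv1, m2))
    q <- normalizeRankFirst(pth)
    isRank <- vapply(q$moves, inherits, TRUE, what = "rankMove")
    expect_equal(pathLength(q), 2L)
    expect_true(treeEqual(q$trees[[1L]], pth$trees[[1L]]))
    expect_true(treeEqual(q$trees[[3L]], pth$trees[[3L]]))
    expect_false(isRank[2L] && !isRank[1L])
    built <- built + 1L
  }
})

test_that("cycle paths realize the permuted edge set in d moves", {
  Tc <- caterpillarTree(defaultLeaves(5))
  p <- cyclePath(Tc, c("l1", "l3"))
  expect_equal(pathLength(p), 2L)

  # independent oracle: rewrite the edge set directly per the cyclic formula
  permutedEdgeOracle <- function(tree, cycle) {
    es <- edgeSet(tree)
    key <- paste(es$parent, es$child)
    par <- function(lab) es$parent[es$child == lab]
    d <- length(cycle)
    drop <- vapply(cycle, function(lab) paste(par(lab), lab), "")
    add <- data.frame(
      parent = c(par(cycle[1L]), vapply(seq_len(d - 1L) + 1L, function(j) par(cycle[j]), "")),
      child = c(cycle[d], cycle[seq_len(d - 1L)]))
    treeFromEdges(rbind(es[!(key %in% drop), ], add))
  }
  expect_true(treeEqual(p$trees[[3L]], permutedEdgeOracle(Tc, c("l1", "l3"))))

  set.seed(27)
  for (rep in 1:25) {
    tr <- randomRankedTree(6)
    st <- edgeSet(tr)
    leafParents <- vapply(leafLabels(tr),
                          function(l) as.integer(st$parent[st$child == l]), 0L)
    lo <- names(sort(leafParents))[1:2]
    if (leafParents[lo[1L]] == leafParents[lo[2L]]) next  # siblings: degenerate
    p <- cyclePath(tr, lo)
    expect_equal(pathLength(p), 2L)
    endpoint <- p$trees[[3L]]
    expect_true(treeEqual(endpoint, permutedEdgeOracle(tr, lo)))
    expect_lte(treeDistance(tr, endpoint, "hspr"), 2L)
  }
  expect_error(cyclePath(Tc, c("l1", "l1")), class = "PreconditionViolated")
  expect_error(cyclePath(Tc, c("l1", "4")), class = "PreconditionViolated")
})
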