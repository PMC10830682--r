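test_that("cluster-list construction validates merges and infers the root", {
  t5 <- counterT()
  expect_equal(nLeaves(t5), 5L)
  expect_equal(clusterString(t5), "[{l1,l2},{l1,l2,l3},{l4,l5},{l1,l2,l3,l4,l5}]")

  t2 <- rankedTree(list(c("l1", "l2")))
  expect_equal(nLeaves(t2), 2L)
  expect_equal(clusterString(t2), "[{l1,l2}]")

  # l1 is already absorbed into {l1,l2} before {l1,l3} could merge
  expect_error(rankedTree(list(c("l1", "l2"), c("l3", "l4"), c("l1", "l3"))),
               class = "MergeInvalid")
  expect_error(rankedTree(list()), class = "EmptyInput")
  expect_error(rankedTree(list(c("l1", "l1"))), class = "DuplicateLeaf")
  expect_error(rankedTree(list(c("1", "l2"), c("1", "l2", "l3"))),
               class = "LabelClash")
})

test_that("invalid rank orderings of valid cluster families are rejected", {
  # swapping two consecutive clusters joined by an edge breaks merge validity
  for (tr in enumerateTrees(4)) {
    cl <- clusterList(tr)
    for (r in 1:2) {
      if (all(cl[[r]] %in% cl[[r + 1L]])) {
        swapped <- cl
        swapped[c(r, r + 1L)] <- swapped[c(r + 1L, r)]
        expect_error(rankedTree(swapped), class = "MergeInvalid")
      }
    }
  }
})

test_that("the labeled edge set is derived correctly and inverts", {
  es <- edgeSet(counterT())
  expect_equal(
    paste(es$parent, es$child),
    c("1 l1", "1 l2", "2 1", "2 l3", "3 l4", "3 l5", "4 2", "4 3"))
  expect_equal(paste(edgeSet(rankedTree(list(c("l1", "l2"))))$child), c("l1", "l2"))

  for (n in 3:8) {
    tr <- randomRankedTree(n, seed = n)
    expect_equal(nrow(edgeSet(tr)), 2L * (n - 1L))
  }
  for (tr in enumerateTrees(5)) {
    expect_true(treeEqual(treeFromEdges(edgeSet(tr)), tr))
  }
})

test_that("rank intervals are the non-edges between consecutive ranks", {
  expect_equal(rankIntervals(fig3Tree()), list(c(2L, 1L), c(3L, 2L)))
  expect_equal(rankIntervals(caterpillarTree(defaultLeaves(5))), list())
  expect_equal(rankIntervals(counterT()), list(c(3L, 2L)))
})

test_that("cherries are the internal nodes with two leaf children", {
  ch <- cherries(counterT())
  expect_equal(lapply(ch, `[[`, "leaves"), list(c("l1", "l2"), c("l4", "l5")))
  expect_equal(vapply(ch, `[[`, 0L, "rank"), c(1L, 3L))
  expect_equal(cherries(rankedTree(list(c("l1", "l2"))))[[1L]]$rank, 1L)
  expect_length(cherries(caterpillarTree(defaultLeaves(5))), 1L)
})

test_that("caterpillar trees stack clusters and have no rank interval", {
  expect_equal(clusterString(caterpillarTree(defaultLeaves(4))),
               "[{l1,l2},{l1,l2,l3},{l1,l2,l3,l4}]")
  expect_equal(clusterString(caterpillarTree(c("l1", "l2"))), "[{l1,l2}]")
  expect_equal(rankIntervals(caterpillarTree(defaultLeaves(6))), list())
  expect_error(caterpillarTree("l1"), class = "EmptyInput")
})

test_that("deleting a rank-one cherry leaf suppresses its parent", {
  out <- deleteCherryLeaf(counterR(), "l5")
  expect_equal(clusterString(out), "[{l2,l3},{l1,l4},{l1,l2,l3,l4}]")

  t3 <- rankedTree(list(c("l1", "l2"), c("l1", "l2", "l3")))
  expect_equal(clusterString(deleteCherryLeaf(t3, "l2")), "[{l1,l3}]")

  expect_error(deleteCherryLeaf(counterT(), "l4"),
               class = "NotRankOneCherryLeaf")
})

test_that("leaf addition matches both printed constructions and inverts", {
  expect_equal(clusterString(addLeaf(caterpillarTree(defaultLeaves(4)), "l5",
                                     "above_root")),
               "[{l1,l2},{l1,l2,l3},{l1,l2,l3,l4},{l1,l2,l3,l4,l5}]")

  base <- lemmaCaterpillarPair(4)$R   # [{l2,l3},{l2,l3,l4},{l1..l4}]
  expect_equal(clusterString(addLeaf(base, "l5", "rank_one_cherry", sibling = "l1")),
               "[{l1,l5},{l2,l3},{l2,l3,l4},{l1,l2,l3,l4,l5}]")

  for (n in 4:7) {
    tr <- randomRankedTree(n, seed = 100 + n)
    grown <- addLeaf(tr, "x9", "rank_one_cherry", sibling = leafLabels(tr)[1L])
    expect_true(treeEqual(deleteCherryLeaf(grown, "x9"), tr))
  }
  expect_error(addLeaf(counterT(), "l1", "above_root"), class = "DuplicateLeaf")
  expect_error(addLeaf(counterT(), "l9", "rank_one_cherry", sibling = "zz"),
               class = "UnknownSibling")
})

test_that("enumeration counts match n!(n-1)!/2^(n-1) with no duplicates", {
  for (n in 2:6) {
    trees <- enumerateTrees(n)
    expect_equal(length(trees), countRankedTrees(n))
    keys <- vapply(trees, clusterString, "")
    expect_false(anyDuplicated(keys) > 0L)
  }
  expect_equal(length(enumerateTrees(2)), 1L)
  expect_equal(length(enumerateTrees(3)), 3L)
  expect_error(enumerateTrees(1), class = "EmptyInput")
})

test_that("the coalescent generator is reproducible and uniform", {
  expect_true(treeEqual(randomRankedTree(6, seed = 42),
                        randomRankedTree(6, seed = 42)))

  # uniformity over the 3 ranked trees on 3 leaves
  set.seed(7)
  keys3 <- vapply(enumerateTrees(3), clusterString, "")
  draws <- replicate(3000, clusterString(randomRankedTree(3)))
  tab <- table(factor(draws, levels = keys3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # coupon collector: all 18 trees on 4 leaves appear
  set.seed(8)
  draws4 <- replicate(18000, clusterString(randomRankedTree(4)))
  expect_equal(length(unique(draws4)), 18L)
})

test_that("unranked topologies forget ranks only", {
  a <- counterT()
  b <- rankedTree(list(c("l4", "l5"), c("l1", "l2"), c("l1", "l2", "l3")))
  expect_true(topologyEqual(a, b))
  expect_false(treeEqual(a, b))
  expect_false(topologyEqual(caterpillarTree(defaultLeaves(4)),
                             rankedTree(list(c("l1", "l2"), c("l3", "l4")))))
})
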