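# Fixture trees used across the suite. All are built in code; the 5-leaf
# pair sharing {l4,l5} is the standard counterexample to the weak cluster
# property, and fig3Tree is the 5-leaf tree with two rank intervals.

counterT <- function() {
  rankedTree(list(c("l1", "l2"), c("l1", "l2", "l3"), c("l4", "l5")))
}

counterR <- function() {
  rankedTree(list(c("l4", "l5"), c("l2", "l3"), c("l1", "l4", "l5")))
}

fig3Tree <- function() {
  parseClusterList("[{l1,l2},{l3,l4},{l1,l2,l5},{l1,l2,l3,l4,l5}]")
}

# caterpillar pair whose leaf parents all differ in rank:
# T = (l1,l2,...,ln), R = (l3,l4,...,ln) with l2 joining at rank 1 and l1
# attached directly below the root
shiftedCaterpillarPair <- function(n) {
  leaves <- defaultLeaves(n)
  Tc <- caterpillarTree(leaves)
  Rc <- rankedTree(c(list(c("l3", "l4")),
                     lapply(seq_len(n - 3L), function(i) leaves[2:(i + 3L)]),
                     list(leaves)),
                   leaves = leaves)
  list(T = Tc, R = Rc)
}

# pair of trees on n+1 leaves obtained from the rotated caterpillar pair by
# the two leaf additions that collapse the distance to one
collapsedPair <- function(n) {
  base <- lemmaCaterpillarPair(n)
  leaf <- paste0("l", n + 1L)
  list(T = addLeaf(base$T, leaf, "above_root"),
       R = addLeaf(base$R, leaf, "rank_one_cherry", sibling = "l1"))
}

randomPair <- function(n) {
  list(a = randomRankedTree(n), b = randomRankedTree(n))
}

hsprDiameterFormula <- function(n) floor(3 * (n - 2) / 2)
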