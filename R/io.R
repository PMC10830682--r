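# Text formats: cluster-list strings and ultrametric Newick.
#
# The cluster-list dialect is `[{l1,l2},{l1,l2,l3},{l4,l5}]` — whitespace
# insensitive, labels alphanumeric (plus "_" and "."), root cluster optional
# on input and always emitted on output. The Newick dialect encodes ranks as
# integer node heights: leaves sit at height 0, the internal node of rank i
# at height i, so every branch length is the rank difference of its
# endpoints. Real-valued ultrametric trees are accepted and rank-ordered;
# tied internal heights are rejected.

#' Parse a cluster-list string
#'
#' @param text a string like `"[{l1,l2},{l1,l2,l3},{l4,l5}]"`.
#' @param leaves optional leaf label set (useful when the root cluster is
#'   omitted and some leaf appears in no printed cluster).
#' @return a `rankedTree`.
#' @export
parseClusterList <- function(text, leaves = NULL) {
  s <- gsub("[[:space:]]", "", text)
  if (!grepl("^\\[.*\\]$", s)) {
    rsprStop("ParseError", "cluster list must be wrapped in [ ]")
  }
  body <- substr(s, 2L, nchar(s) - 1L)
  if (nchar(body) == 0L) rsprStop("EmptyInput", "empty cluster list")
  m <- gregexpr("\\{[^{}]*\\}", body)[[1L]]
  if (m[1L] == -1L) rsprStop("ParseError", "no {...} clusters found")
  covered <- sum(attr(m, "match.length"))
  seps <- nchar(body) - covered
  if (seps != length(m) - 1L) {
    rsprStop("ParseError", "malformed cluster list")
  }
  clusters <- lapply(regmatches(body, gregexpr("\\{[^{}]*\\}", body))[[1L]],
                     function(grp) {
    inner <- substr(grp, 2L, nchar(grp) - 1L)
    if (nchar(inner) == 0L) rsprStop("ParseError", "empty cluster")
    labs <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    if (any(labs == "") || any(!grepl("^[A-Za-z0-9_.]+$", labs))) {
      rsprStop("ParseError", paste0("bad leaf label in ", grp))
    }
    labs
  })
  rankedTree(clusters, leaves = leaves)
}

#' Write the cluster-list string of a tree
#'
#' Alias of [clusterString()]: canonical dialect, root emitted, leaves
#' sorted within clusters.
#' @param tree a `rankedTree`.
#' @return a single string.
#' @export
writeClusterList <- function(tree) clusterString(tree)

#' Parse an ultrametric Newick string into a ranked tree
#'
#' The tree must be rooted, binary and ultrametric (all leaves at the same
#' height, within `tol`); internal node heights must be strictly ordered and
#' are mapped to ranks `1..n-1` in ascending order. Integer heights equal to
#' the ranks round-trip losslessly through [writeNewick()].
#' @param text a Newick string (with branch lengths).
#' @param tol tolerance used for the leaf-height (ultrametricity) check and
#'   for declaring two internal heights tied (tied heights are an error).
#' @return a `rankedTree`.
#' @export
parseNewick <- function(text, tol = 1e-8) {
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy) || is.null(phy$edge.length)) {
    rsprStop("ParseError", "not a parsable Newick string with branch lengths")
  }
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    rsprStop("NotBinary", "tree must be rooted and binary")
  }
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)   # root = 0, increasing to tips
  tipDepth <- depth[seq_len(n)]
  if (max(tipDepth) - min(tipDepth) > tol) {
    rsprStop("NotUltrametric", "leaves are not at equal height")
  }
  height <- max(tipDepth) - depth
  internal <- (n + 1L):(n + phy$Nnode)
  h <- height[internal]
  if (any(diff(sort(h)) <= tol)) {
    rsprStop("TiedInternalHeights", "internal node heights must be strictly ordered")
  }
  ranks <- rank(h)
  clades <- lapply(internal, function(nd) {
    ape::extract.clade(phy, nd)$tip.label
  })
  rankedTree(clades[order(ranks)], leaves = phy$tip.label)
}

#' Write a ranked tree as ultrametric Newick
#'
#' Inverse of [parseNewick()] on the canonical dialect: leaf branches have
#' length equal to the parent rank, internal branches the rank difference.
#' Children are ordered by their smallest leaf label for a deterministic
#' output.
#' @param tree a `rankedTree`.
#' @return a Newick string (with trailing `;`).
#' @export
writeNewick <- function(tree) {
  n <- nLeaves(tree)
  st <- treeStructure(tree$clusters, n)
  build <- function(id) {
    if (id < 0L) return(list(text = tree$labels[-id], h = 0L))
    kids <- lapply(st$childId[, id], build)
    kids <- kids[order(vapply(kids, function(k) k$text, ""))]
    list(text = paste0("(", kids[[1L]]$text, ":", id - kids[[1L]]$h, ",",
                       kids[[2L]]$text, ":", id - kids[[2L]]$h, ")"),
         h = id)
  }
  paste0(build(n - 1L)$text, ";")
}

#' Read one or more trees from text or a file
#'
#' Dispatch helper used by the command line: an argument starting with `[`
#' is parsed as a cluster-list literal, one containing `(` as a Newick
#' literal, anything else as a path to a file holding one tree per line
#' (either dialect, blank lines and `#` comments skipped).
#' @param x a string (literal or file path).
#' @return list of `rankedTree` objects.
#' @export
readTrees <- function(x) {
  parseOne <- function(s) {
    if (startsWith(trimws(s), "[")) parseClusterList(s) else parseNewick(s)
  }
  s <- trimws(x)
  if (startsWith(s, "[") || grepl("(", s, fixed = TRUE)) {
    return(list(parseOne(s)))
  }
  if (!file.exists(x)) rsprStop("ParseError", paste0("no such file: ", x))
  lines <- trimws(readLines(x, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parseOne)
}
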