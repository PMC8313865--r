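# Independent brute-force oracles used to cross-check the package's
# bipartition, support and tree-comparison machinery, plus tiny fixtures.
# These deliberately avoid the package's own tree_bipartitions/compute
# paths: clades are enumerated by direct recursion over the edge table.

# descendants of every edge's child node, by plain recursion
oracle_edge_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply(tree$edge[, 2], desc)
}

# brute-force transfer distance: min Hamming over every edge bipartition
# of `tree` and both labelings
oracle_transfer_distance <- function(side_a, tree) {
  leaves <- sort(tree$tip.label)
  b <- leaves %in% side_a
  dists <- vapply(oracle_edge_clades(tree), function(cl) {
    v <- leaves %in% cl
    h <- sum(v != b)
    min(h, length(leaves) - h)
  }, numeric(1))
  # also the root "clade" (all leaves), equivalent to the empty side
  h0 <- min(sum(b), length(leaves) - sum(b))
  min(c(dists, h0))
}

# brute-force TBE for every internal branch of `ref` with light side >= 2
oracle_tbe <- function(ref, reps) {
  leaves <- sort(ref$tip.label)
  ntip <- length(leaves)
  clades <- oracle_edge_clades(ref)
  keep <- vapply(clades, function(cl) {
    p <- min(length(cl), ntip - length(cl))
    p >= 2
  }, logical(1))
  clades <- clades[keep]
  res <- lapply(clades, function(cl) {
    p <- min(length(cl), ntip - length(cl))
    d <- vapply(reps, function(tr) oracle_transfer_distance(cl, tr),
                numeric(1))
    other <- setdiff(leaves, cl)
    side <- if (length(cl) < length(other)) cl
      else if (length(cl) > length(other)) other
      else if (leaves[1] %in% cl) other else cl   # tie: side without 1st leaf
    data.frame(side = paste(sort(side), collapse = ","),
               p = p, tbe = 1 - mean(d) / (p - 1))
  })
  out <- do.call(rbind, res)
  unique(out)
}

# rooted triple topology via tree pruning: returns "star" or the cherry
# pair "x|y" (sorted), independently of the package's mrca-depth route
oracle_triple_topology <- function(tree, trio) {
  tr3 <- ape::keep.tip(tree, trio)
  tr3 <- ape::collapse.singles(tr3)
  if (tr3$Nnode < 2L) return("star")
  ntip <- 3L
  # the cherry is the pair whose parent is not the root
  root <- setdiff(tr3$edge[, 1], tr3$edge[, 2])
  parents <- tr3$edge[match(1:3, tr3$edge[, 2]), 1]
  cherry <- tr3$tip.label[parents != root]
  paste(sort(cherry), collapse = "|")
}

oracle_triples_distance <- function(t1, t2) {
  leaves <- sort(t1$tip.label)
  trios <- combn(leaves, 3, simplify = FALSE)
  diffs <- vapply(trios, function(tri) {
    oracle_triple_topology(t1, tri) != oracle_triple_topology(t2, tri)
  }, logical(1))
  mean(diffs)
}

# exact hypergeometric upper tail by direct summation over choose()
oracle_hyper_upper <- function(k, K, N, n) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# small fixed panel with distinctive flanks for read-mapping tests
toy_panel <- function() {
  validate_panel(data.frame(
    locus_id = c("locA", "locB"),
    chrom = "chrX",
    start = c(0L, 0L),
    end = c(26L, 30L),
    unit = c("AC", "AC"),
    ref_repeat_count = c(13L, 15L),
    flank_left = c("TGGATCCAGTAACGTTAGCC", "CCGATAGCTTGACCATGGTA"),
    flank_right = c("GGTACCTAGGCATCGATTGA", "TTGCAGGCTAACCGGTTCAA"),
    stringsAsFactors = FALSE
  ))
}

random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

random_unrooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}
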