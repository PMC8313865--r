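# Tree reconstruction and rooting.  The reconstructor is neighbor joining
# on the mutation-count distance matrix; the matrix itself is the central
# object and can be exported (write_phylip) for external distance-based
# tree builders.

#' Build a neighbor-joining lineage tree
#'
#' Runs neighbor joining on a mutation-count distance matrix.  Cells are
#' ordered lexicographically before agglomeration so that ties are broken
#' deterministically; negative branch lengths (a known NJ artifact) are
#' clamped to zero with a warning.
#'
#' @param d \code{\link{mutation_count_distance}} result or a symmetric
#'   numeric matrix with cell dimnames.
#' @return unrooted \code{phylo} tree.
#' @export
build_nj_tree <- function(d) {
  D <- if (inherits(d, "mutation_dist")) d$distance else as.matrix(d)
  if (anyNA(D)) stop("distance matrix has undefined entries; cannot run NJ")
  if (nrow(D) < 3L) {
    # degenerate: 2 taxa joined by a single edge
    tr <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = rownames(D), Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("clamping ", sum(tr$edge.length < 0),
            " negative NJ branch lengths to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a lineage tree at the median genotype of a group
#'
#' Two modes. \code{"outgroup"}: the median genotype of \code{group} is
#' appended to the genotype matrix as a synthetic outgroup taxon, the tree
#' is rebuilt including it, rooted on that taxon and the taxon dropped --
#' this re-estimates the topology jointly with the root.  Default
#' \code{"nearest_edge"}: the existing unrooted tree is kept and rooted on
#' the edge whose bipartition minimizes the mean attachment residual of the
#' median genotype, i.e. \code{mean d(v, A) + mean d(v, B) - mean
#' patristic(A, B)} over the edge's split A|B, where d(v, .) are
#' mutation-count distances from the median genotype to each cell.
#'
#' @param tree unrooted \code{phylo} (ignored in outgroup mode).
#' @param m genotype matrix used to build the tree.
#' @param group cell ids whose median genotype approximates the root, or a
#'   genotype vector (named by pseudo-locus) to use directly.
#' @param method "nearest_edge" (default) or "outgroup".
#' @param normalize,min_shared passed to
#'   \code{\link{mutation_count_distance}}.
#' @return rooted \code{phylo}; attribute \code{"root_method"} records the
#'   placement mode.
#' @export
root_tree <- function(tree, m, group, method = c("nearest_edge", "outgroup"),
                      normalize = TRUE, min_shared = 50L) {
  method <- match.arg(method)
  root_geno <- if (is.character(group)) median_genotype(m, group) else group
  if (length(root_geno) != ncol(m)) {
    stop("root genotype length does not match matrix columns")
  }
  aug <- rbind(m, "..root.." = root_geno)
  if (method == "outgroup") {
    d <- mutation_count_distance(aug, normalize = normalize,
                                 min_shared = min_shared)
    tr <- build_nj_tree(d)
    tr <- ape::root(tr, outgroup = "..root..", resolve.root = TRUE)
    tr <- ape::drop.tip(tr, "..root..")
    # drop.tip can leave an unresolved basal node; re-root cleanly
    attr(tr, "root_method") <- "outgroup"
    return(tr)
  }
  # nearest-edge placement on the existing topology
  tips <- tree$tip.label
  dv <- vapply(tips, function(cell) {
    sh <- !is.na(m[cell, ]) & !is.na(root_geno)
    s <- sum(sh)
    if (s == 0L) return(NA_real_)
    d <- sum(m[cell, sh] != root_geno[sh])
    if (normalize) d / s else d
  }, numeric(1))
  if (anyNA(dv)) stop("median genotype shares no loci with some cells")
  pat <- ape::cophenetic.phylo(tree)[tips, tips]
  ntip <- length(tips)
  best <- NULL; best_score <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    clade <- if (child <= ntip) tips[child] else
      ape::extract.clade(tree, child)$tip.label
    other <- setdiff(tips, clade)
    if (!length(other)) next
    score <- mean(dv[clade]) + mean(dv[other]) -
      mean(pat[clade, other, drop = FALSE])
    if (score < best_score - 1e-12 ||
        (abs(score - best_score) <= 1e-12 && is.null(best))) {
      best_score <- score; best <- e
    }
  }
  child <- tree$edge[best, 2]
  # bisect the chosen edge so the new root lies on it
  tr <- phytools::reroot(tree, child, position = tree$edge.length[best] / 2)
  attr(tr, "root_method") <- "nearest_edge"
  attr(tr, "root_edge_score") <- best_score
  tr
}

#' Write an annotated Newick file
#'
#' Node labels, when provided, are written as Newick internal-node labels of
#' the form \code{support|enrichment}.
#'
#' @param tree \code{phylo}.
#' @param path output path.
#' @param node_labels optional character vector over internal nodes.
#' @export
write_lineage_newick <- function(tree, path, node_labels = NULL) {
  if (!is.null(node_labels)) tree$node.label <- node_labels
  ape::write.tree(tree, file = path)
  invisible(path)
}
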