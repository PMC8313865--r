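# Rooted-tree comparison by the normalized triples distance, and the
# coverage-subsampling analysis built on it.

# per-tree preprocessing for triples: topological depths of every node and
# the MRCA matrix over a fixed leaf ordering
triple_codes <- function(tree, leaves) {
  # the tree is interpreted as rooted at its root node; a basal polytomy
  # simply leaves the triples it spans unresolved
  idx <- match(leaves, tree$tip.label)
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  depth <- ape::node.depth.edgelength(t1)
  M <- ape::mrca(tree)[idx, idx]
  list(depth = depth, mrca = M)
}

# induced topology code for each leaf triple: 0 = unresolved (star),
# 1/2/3 = the pair (ab / ac / bc) that is the cherry
code_triples <- function(prep, trip) {
  a <- trip[1, ]; b <- trip[2, ]; c <- trip[3, ]
  dab <- prep$depth[prep$mrca[cbind(a, b)]]
  dac <- prep$depth[prep$mrca[cbind(a, c)]]
  dbc <- prep$depth[prep$mrca[cbind(b, c)]]
  top <- pmax(dab, dac, dbc)
  code <- integer(length(a))
  resolved_ab <- dab == top & dac < top & dbc < top
  resolved_ac <- dac == top & dab < top & dbc < top
  resolved_bc <- dbc == top & dab < top & dac < top
  code[resolved_ab] <- 1L
  code[resolved_ac] <- 2L
  code[resolved_bc] <- 3L
  code
}

#' Normalized triples distance between two rooted trees
#'
#' Over all C(n, 3) leaf triples, counts triples whose induced rooted
#' topology (which pair coalesces last, or unresolved) differs between the
#' trees, normalized by the number of triples.  By default an unresolved
#' (polytomous) triple counts as different from any resolved one;
#' \code{resolved_only = TRUE} restricts the comparison (and the
#' denominator) to triples resolved in both trees.
#'
#' @param t1,t2 rooted \code{phylo} trees on identical leaf sets.
#' @param resolved_only compare only mutually resolved triples.
#' @return distance in [0, 1].
#' @export
triples_distance <- function(t1, t2, resolved_only = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  leaves <- sort(t1$tip.label)
  n <- length(leaves)
  if (n < 3L) return(0)
  p1 <- triple_codes(t1, leaves)
  p2 <- triple_codes(t2, leaves)
  trip <- combn(n, 3L)
  c1 <- code_triples(p1, trip)
  c2 <- code_triples(p2, trip)
  if (resolved_only) {
    keep <- c1 != 0L & c2 != 0L
    if (!any(keep)) return(0)
    return(sum(c1[keep] != c2[keep]) / sum(keep))
  }
  sum(c1 != c2) / ncol(trip)
}

#' Coverage-subsampling reconstruction-stability curve
#'
#' For each coverage value, repeatedly subsamples the dataset's histograms,
#' re-genotypes, rebuilds the rooted tree and measures the normalized
#' triples distance to the tree reconstructed from the full data.
#'
#' @param dataset output of \code{\link{generate_dataset}}.
#' @param coverages integer vector of target per-locus coverages.
#' @param B_per_point subsampling replicates per coverage (default 3).
#' @param min_coverage,confidence_threshold genotyping thresholds.
#' @param min_shared passed to \code{\link{mutation_count_distance}}.
#' @param seed optional seed.
#' @return data.frame: coverage, mean_distance, sd_distance, n_replicates.
#' @export
coverage_curve <- function(dataset, coverages, B_per_point = 3L,
                           min_coverage = 10L, confidence_threshold = 0.05,
                           min_shared = 50L, seed = NULL) {
  set_seed_if(seed)
  panel <- dataset$truth$panel
  root_geno <- setNames(as.integer(panel$ref_repeat_count), panel$locus_id)
  rebuild <- function(hists) {
    calls <- call_genotypes(hists, dataset$model, panel,
                            min_coverage = min_coverage,
                            confidence_threshold = confidence_threshold)
    m <- assemble_matrix(calls)
    root_tree(NULL, m, root_geno[colnames(m)], method = "outgroup",
              min_shared = min_shared)
  }
  full_tree <- rebuild(dataset$histograms)
  rows <- lapply(coverages, function(cv) {
    d <- vapply(seq_len(B_per_point), function(b) {
      sub <- subsample_histograms(dataset$histograms, target_coverage = cv)
      triples_distance(rebuild(sub), full_tree)
    }, numeric(1))
    data.frame(coverage = cv, mean_distance = mean(d),
               sd_distance = if (length(d) > 1) sd(d) else NA_real_,
               n_replicates = B_per_point)
  })
  do.call(rbind, rows)
}
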