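# Branch support and clade enrichment: loci-subsampling bootstrap,
# transfer bootstrap expectation (TBE), per-branch hypergeometric tests.

# all non-trivial bipartitions of a tree as a logical matrix
# (rows = branches, columns = leaves in the order `leaves`); rows are
# oriented so the TRUE side excludes the first leaf
tree_bipartitions <- function(tree, leaves = NULL, keep_trivial = FALSE) {
  if (is.null(leaves)) leaves <- sort(tree$tip.label)
  if (!setequal(leaves, tree$tip.label)) {
    stop("tree leaves do not match the requested leaf set")
  }
  n <- length(leaves)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  rows <- list()
  for (cl in pp) {
    v <- logical(n)
    v[match(labs[cl], leaves)] <- TRUE
    if (sum(v) %in% c(0L, n)) next                  # root/full clade
    if (!keep_trivial && min(sum(v), n - sum(v)) < 2L) next
    if (v[1]) v <- !v
    rows[[length(rows) + 1L]] <- v
  }
  if (keep_trivial) {
    for (i in seq_len(n)) {
      v <- logical(n); v[i] <- TRUE
      if (v[1]) v <- !v
      rows[[length(rows) + 1L]] <- v
    }
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(logical(0), 0, n)
  colnames(mat) <- leaves
  unique(mat)
}

#' Loci-subsampling bootstrap replicates
#'
#' Each replicate keeps \code{ceiling(keep_fraction * ncol(m))} pseudo-locus
#' columns drawn without replacement (the default 2/3 leaves out about a
#' third of the loci at every round), recomputes the mutation-count
#' distance matrix and rebuilds the NJ tree.
#'
#' @param m genotype matrix.
#' @param keep_fraction fraction of columns kept per replicate (default 2/3).
#' @param B number of replicates (default 100).
#' @param normalize,min_shared passed to
#'   \code{\link{mutation_count_distance}}.
#' @param seed optional seed.
#' @return list of unrooted \code{phylo} replicates (replicates whose
#'   subsample leaves some pair without enough shared loci are skipped with
#'   a warning).
#' @export
bootstrap_replicates <- function(m, keep_fraction = 2 / 3, B = 100L,
                                 normalize = TRUE, min_shared = 50L,
                                 seed = NULL) {
  set_seed_if(seed)
  if (B < 1L) stop("B must be >= 1")
  L <- ncol(m)
  k <- ceiling(keep_fraction * L)
  if (k < 1L) stop("keep_fraction leaves no columns")
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, k)
    tr <- tryCatch({
      d <- mutation_count_distance(m[, cols, drop = FALSE],
                                   normalize = normalize,
                                   min_shared = min(min_shared, k))
      t0 <- build_nj_tree(d)
      attr(t0, "n_columns") <- length(cols)
      t0
    }, error = function(e) {
      warning("replicate ", b, " skipped: ", conditionMessage(e))
      NULL
    })
    reps[[b]] <- tr
  }
  Filter(Negate(is.null), reps)
}

#' Transfer distance of a bipartition to a tree
#'
#' Minimum, over all branches of \code{tree} (including trivial
#' single-leaf branches) and both side-labelings, of the Hamming distance
#' between the given bipartition and the branch's bipartition.  Zero iff
#' the bipartition occurs in the tree; at most p - 1 where p is the light
#' side of the bipartition.
#'
#' @param split logical vector over the sorted leaf set (TRUE = one side),
#'   or a two-sided character list of leaf ids.
#' @param tree \code{phylo} on the same leaves.
#' @return integer transfer distance.
#' @export
transfer_distance <- function(split, tree) {
  leaves <- sort(tree$tip.label)
  if (is.list(split)) {
    v <- leaves %in% split[[1]]
    names(v) <- leaves
    split <- v
  }
  if (length(split) != length(leaves)) stop("split length must equal leaf count")
  cand <- tree_bipartitions(tree, leaves, keep_trivial = TRUE)
  ham <- rowSums(cand != matrix(split, nrow(cand), length(leaves),
                                byrow = TRUE))
  min(pmin(ham, length(leaves) - ham))
}

#' Transfer bootstrap expectation (TBE) branch support
#'
#' For each internal branch b of the reference tree with light-side size
#' p >= 2, TBE = 1 - mean_r(delta(b, T_r)) / (p - 1), where delta is the
#' transfer distance to bootstrap replicate T_r.  Values are reported in
#' [0, 1] and as percent.
#'
#' @param ref reference tree (\code{phylo}); may equally be a truth tree
#'   whose splits are to be scored against replicates.
#' @param reps list of replicate trees on the same leaf set.
#' @return data.frame with one row per internal branch: \code{branch_id}
#'   (bipartition hash), \code{p} (light-side size), \code{mean_transfer},
#'   \code{tbe}, \code{tbe_percent}, \code{side} (comma-joined light-side
#'   leaves).
#' @export
compute_tbe <- function(ref, reps) {
  leaves <- sort(ref$tip.label)
  for (r in reps) {
    if (!setequal(r$tip.label, leaves)) {
      stop("replicate leaf set differs from the reference tree")
    }
  }
  splits <- tree_bipartitions(ref, leaves)
  keep <- pmin(rowSums(splits), length(leaves) - rowSums(splits)) >= 2L
  splits <- splits[keep, , drop = FALSE]
  if (!nrow(splits)) {
    return(data.frame(branch_id = character(0), p = integer(0),
                      mean_transfer = numeric(0), tbe = numeric(0),
                      tbe_percent = numeric(0), side = character(0)))
  }
  # per replicate, distances of every ref split to every candidate branch
  delta <- matrix(0, nrow(splits), length(reps))
  for (j in seq_along(reps)) {
    cand <- tree_bipartitions(reps[[j]], leaves, keep_trivial = TRUE)
    cross <- splits %*% t(cand)               # TRUE/TRUE agreements
    rs <- rowSums(splits); cs <- rowSums(cand)
    ham <- outer(rs, cs, "+") - 2 * cross     # Hamming same-orientation
    ham <- pmin(ham, length(leaves) - ham)    # best orientation
    delta[, j] <- apply(ham, 1, min)
  }
  p <- pmin(rowSums(splits), length(leaves) - rowSums(splits))
  mean_d <- rowMeans(delta)
  tbe <- 1 - mean_d / (p - 1)
  side <- apply(splits, 1, function(v) {
    s <- if (sum(v) <= length(v) - sum(v)) leaves[v] else leaves[!v]
    paste(s, collapse = ",")
  })
  data.frame(branch_id = vapply(side, function(s)
    sprintf("b%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFF),
    character(1), USE.NAMES = FALSE),
    p = as.integer(p), mean_transfer = mean_d, tbe = tbe,
    tbe_percent = 100 * tbe, side = side, stringsAsFactors = FALSE)
}

#' Hypergeometric clade-enrichment tests
#'
#' For every internal branch of a rooted tree and every population label,
#' tests whether the branch's subtree leaves are enriched for that label:
#' upper-tail hypergeometric p-value of drawing at least k label leaves in
#' n subtree leaves from N labeled leaves of which K carry the label.
#' Benjamini-Hochberg adjustment is applied across all (branch, label)
#' tests; unlabeled leaves are excluded from the universe with a warning.
#'
#' @param tree rooted \code{phylo}.
#' @param labels named character/factor vector, cell id -> population label.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return data.frame: branch_id, label, k, n, K, N, p_value, adjusted_p,
#'   significant, side (subtree leaves).
#' @export
hypergeometric_enrichment <- function(tree, labels, alpha = 0.05) {
  labels <- setNames(as.character(labels), names(labels))
  tips <- tree$tip.label
  unl <- setdiff(tips, names(labels)[!is.na(labels)])
  if (length(unl)) {
    warning("excluding ", length(unl), " unlabeled leaves from the universe")
  }
  universe <- intersect(tips, names(labels)[!is.na(labels)])
  N <- length(universe)
  ntip <- length(tips)
  rows <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    clade <- ape::extract.clade(tree, node)$tip.label
    sub <- intersect(clade, universe)
    n <- length(sub)
    if (n == 0L) next
    for (lab in unique(labels[universe])) {
      K <- sum(labels[universe] == lab)
      k <- sum(labels[sub] == lab)
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        branch_id = sprintf("n%d", node), label = lab,
        k = k, n = n, K = K, N = N, p_value = p,
        side = paste(sort(sub), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}
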