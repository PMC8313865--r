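# Bootstrap replicates, transfer distance, TBE, hypergeometric enrichment.

sim_matrix <- function(n_loci = 200, seed = 61) {
  tr <- simulate_benchmark_tree(levels = 4, branching = 2, seed = seed)
  panel <- synthetic_panel(n_loci, seed = seed)
  ds <- generate_dataset(tr, panel, zero_stutter_model(), coverage = 15,
                         rate = 2e-2, seed = seed)
  calls <- call_genotypes(ds$histograms, zero_stutter_model(), panel)
  list(m = assemble_matrix(calls), truth = ds$truth)
}

test_that("bootstrap replicates keep ceiling(2/3 L) columns and are seeded", {
  s <- sim_matrix()
  reps <- bootstrap_replicates(s$m, B = 5L, min_shared = 20L, seed = 62)
  expect_length(reps, 5L)
  for (r in reps) {
    expect_equal(attr(r, "n_columns"), ceiling(2 / 3 * ncol(s$m)))
  }
  reps2 <- bootstrap_replicates(s$m, B = 5L, min_shared = 20L, seed = 62)
  expect_identical(lapply(reps, ape::write.tree),
                   lapply(reps2, ape::write.tree))
})

test_that("keep_fraction = 1 reproduces the full tree in every replicate", {
  s <- sim_matrix()
  full <- build_nj_tree(mutation_count_distance(s$m, min_shared = 20L))
  reps <- bootstrap_replicates(s$m, keep_fraction = 1, B = 3L,
                               min_shared = 20L, seed = 63)
  for (r in reps) {
    expect_equal(ape::dist.topo(full, r), setNames(0, "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("transfer distance is 0 for present splits and matches a cherry example", {
  tr <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  leaves <- sort(tr$tip.label)
  # a split present in the tree
  expect_equal(transfer_distance(list(c("a", "b")), tr), 0L)
  # cherry (a,b) against a tree with cherry (a,c) on 5 leaves -> 1
  tr2 <- ape::read.tree(text = "((a,c),(b,(d,e)));")
  expect_equal(transfer_distance(list(c("a", "b")), tr2), 1L)
})

test_that("transfer distance equals the brute-force oracle on random trees", {
  for (seed in 1:6) {
    t_ref <- random_unrooted_tree(8, seed)
    t_cmp <- random_unrooted_tree(8, seed + 100)
    leaves <- sort(t_ref$tip.label)
    clades <- oracle_edge_clades(t_ref)
    for (cl in clades) {
      p <- min(length(cl), 8 - length(cl))
      if (p < 2) next
      v <- leaves %in% cl
      expect_equal(transfer_distance(setNames(v, leaves), t_cmp),
                   oracle_transfer_distance(cl, t_cmp))
      expect_lte(transfer_distance(setNames(v, leaves), t_cmp), p - 1)
    }
  }
})

test_that("TBE is 1 for reproduced branches and floors at 0", {
  tr <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  tbe <- compute_tbe(tr, rep(list(tr), 10))
  expect_true(all(tbe$tbe == 1))
  expect_true(all(tbe$p >= 2))
  # a p = 2 branch absent from every replicate with delta = 1 -> tbe = 0
  alt <- ape::read.tree(text = "((a,c),(b,(d,e)));")
  tbe2 <- compute_tbe(tr, rep(list(alt), 10))
  row_ab <- tbe2[tbe2$side == "a,b", ]
  expect_equal(row_ab$tbe, 0)
  expect_error(compute_tbe(tr, list(ape::read.tree(text = "((a,b),(c,d));"))),
               "leaf set")
})

test_that("TBE equals the brute-force oracle on random 6-leaf cases", {
  for (seed in 1:4) {
    t_ref <- random_unrooted_tree(6, seed)
    reps <- lapply(1:5, function(i) random_unrooted_tree(6, seed * 10 + i))
    got <- compute_tbe(t_ref, reps)
    want <- oracle_tbe(t_ref, reps)
    got <- got[order(got$side), ]
    want <- want[order(want$side), ]
    expect_equal(got$side, want$side)
    expect_equal(got$tbe, want$tbe, tolerance = 1e-12)
    expect_true(all(got$tbe >= 0 & got$tbe <= 1))
  }
})

test_that("appending the reference as a replicate never decreases TBE", {
  t_ref <- random_unrooted_tree(7, 71)
  reps <- lapply(1:4, function(i) random_unrooted_tree(7, 700 + i))
  base <- compute_tbe(t_ref, reps)
  more <- compute_tbe(t_ref, c(reps, list(t_ref)))
  ord <- order(base$side)
  expect_true(all(more$tbe[order(more$side)] >= base$tbe[ord] - 1e-12))
})

test_that("hypergeometric enrichment matches exact tail sums", {
  # 10 leaves, 5 labeled "x", a clade of exactly those 5
  tr <- ape::read.tree(
    text = "(((x1,x2),(x3,(x4,x5))),((y1,y2),(y3,(y4,y5))));")
  labels <- setNames(rep(c("x", "y"), each = 5),
                     c(paste0("x", 1:5), paste0("y", 1:5)))
  enr <- hypergeometric_enrichment(tr, labels)
  perfect <- enr[enr$k == 5 & enr$n == 5 & enr$label == "x", ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$p_value, 1 / choose(10, 5))       # 1/252
  expect_equal(perfect$p_value, oracle_hyper_upper(5, 5, 10, 5),
               tolerance = 1e-15)
  # the root's subtree is everything: p = 1
  root_rows <- enr[enr$n == 10, ]
  expect_true(all(root_rows$p_value == 1))
  # survival identity against exact summation across all records
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p_value[i],
                 oracle_hyper_upper(enr$k[i], enr$K[i], enr$N[i], enr$n[i]),
                 tolerance = 1e-12)
  }
  # label renaming leaves p-values unchanged
  lab2 <- setNames(ifelse(labels == "x", "alpha", "beta"), names(labels))
  enr2 <- hypergeometric_enrichment(tr, lab2)
  expect_equal(sort(enr2$p_value), sort(enr$p_value))
})

test_that("permutation null p-values are valid (super-uniform)", {
  tr <- random_rooted_tree(12, 81)
  base_labels <- rep(c("g1", "g2"), each = 6)
  set.seed(82)
  # p-value of one fixed internal branch/label combination under label
  # permutation; a valid test has P(p <= alpha) <= alpha
  pvals <- replicate(400, {
    lab <- setNames(sample(base_labels), tr$tip.label)
    enr <- hypergeometric_enrichment(tr, lab)
    enr$p_value[enr$label == "g1"][2]
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha / 400))
  }
})

test_that("unlabeled leaves are excluded from the universe with a warning", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  labels <- setNames(c("x", "x", "y"), c("a", "b", "c"))
  expect_warning(enr <- hypergeometric_enrichment(tr, labels), "unlabeled")
  expect_true(all(enr$N == 3))
})
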