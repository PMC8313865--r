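# Mutation-count distances, NJ reconstruction, median-genotype rooting.

test_that("mutation-count distance counts differing shared loci", {
  m <- rbind(
    a = c(13L, 14L, 15L, 16L, 17L, 11L, 12L, 13L, 14L, 15L),
    b = c(13L, 14L, 15L, 16L, 17L, 11L, 12L, 13L, 14L, 15L),
    c = c(12L, 14L, 16L, 16L, 17L, 11L, 12L, 13L, 14L, 14L))
  colnames(m) <- sprintf("L%02d", 1:10)
  d <- mutation_count_distance(m, min_shared = 5L)
  expect_equal(d$distance["a", "b"], 0)
  expect_equal(d$distance["a", "c"], 3 / 10)      # 3 of 10 shared differ
  raw <- mutation_count_distance(m, normalize = FALSE, min_shared = 5L)
  expect_equal(raw$distance["a", "c"], 3)
  expect_equal(diag(d$distance), setNames(rep(0, 3), rownames(m)))
  expect_true(isSymmetric(d$distance))
  # invariant under column permutation
  perm <- sample(ncol(m))
  d2 <- mutation_count_distance(m[, perm], min_shared = 5L)
  expect_equal(d2$distance, d$distance)
})

test_that("missing data defines shared counts and the min_shared rule", {
  m <- rbind(a = c(13L, 14L, NA, NA), b = c(13L, 15L, 12L, NA),
             c = c(NA, NA, 12L, 19L))
  colnames(m) <- sprintf("L%d", 1:4)
  d <- mutation_count_distance(m, min_shared = 1L)
  expect_equal(d$shared["a", "b"], 2L)
  expect_equal(d$distance["a", "b"], 1 / 2)
  # a/c share nothing: undefined, and the graph stays connected through b
  expect_true(is.na(d$distance["a", "c"]))
  # raising min_shared disconnects the graph -> error
  expect_error(mutation_count_distance(m, min_shared = 3L), "disconnected")
})

test_that("NJ recovers the topology generating an additive matrix", {
  gen <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:1):2);")
  D <- ape::cophenetic.phylo(gen)
  tr <- build_nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(gen), tr), setNames(0, "PH85"),
               ignore_attr = TRUE)
  # row order does not change the result beyond the documented tie-break
  ord <- c("c", "a", "d", "b")
  tr2 <- build_nj_tree(D[ord, ord])
  expect_equal(ape::dist.topo(tr, tr2), setNames(0, "PH85"),
               ignore_attr = TRUE)
})

test_that("degenerate and negative-branch cases are handled", {
  D2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- build_nj_tree(D2)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sum(tr$edge.length), 4)
  # a strongly non-additive matrix triggers negative-branch clamping
  D <- matrix(c(0, 1, 10, 10,
                1, 0, 1, 10,
                10, 1, 0, 1,
                10, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr4 <- build_nj_tree(D), "clamping")
  expect_true(all(tr4$edge.length >= 0))
})

test_that("median genotype uses the lower median and handles missingness", {
  m <- rbind(a = c(12L, 12L, 10L), b = c(13L, 14L, NA),
             c = c(20L, NA, NA))
  colnames(m) <- c("L1", "L2", "L3")
  med <- median_genotype(m, c("a", "b", "c"))
  expect_equal(unname(med), c(13L, 12L, 10L))    # {12,13,20}->13; {12,14}->12
  expect_equal(unname(median_genotype(m, "b")), c(13L, 14L, NA))
  expect_error(median_genotype(m, character(0)), "non-empty")
  expect_error(median_genotype(m, "zz"), "zz")
})

test_that("rooting modes agree on clade memberships on clean balanced data", {
  tr_true <- simulate_benchmark_tree(levels = 4, branching = 2, seed = 51)
  panel <- synthetic_panel(800, seed = 51)
  ds <- generate_dataset(tr_true, panel, zero_stutter_model(), coverage = 20,
                         rate = 2e-2, seed = 51)
  calls <- call_genotypes(ds$histograms, zero_stutter_model(), panel)
  m <- assemble_matrix(calls)
  d <- mutation_count_distance(m, min_shared = 50L)
  tr <- build_nj_tree(d)
  root_geno <- setNames(as.integer(panel$ref_repeat_count),
                        panel$locus_id)[colnames(m)]
  r1 <- root_tree(tr, m, root_geno)
  r2 <- root_tree(tr, m, root_geno, method = "outgroup")
  expect_true(ape::is.rooted(r1))
  expect_true(ape::is.rooted(r2))
  expect_equal(attr(r1, "root_method"), "nearest_edge")
  # both modes recover the same rooted clade structure
  expect_equal(triples_distance(r1, r2), 0)
  # rooting the already-rooted tree again is idempotent on clades
  r1b <- root_tree(r1, m, root_geno)
  expect_equal(triples_distance(r1, r1b), 0)
  # the root-side bipartition separates the two first-level clades
  lvl1 <- Filter(function(cl) length(cl) == 4,
                 oracle_edge_clades(tr_true))
  for (cl in lvl1) expect_true(ape::is.monophyletic(r1, cl))
})

test_that("rooting at a population group places it basally", {
  spec <- data.frame(label = c("PBL", "Met"), n_cells = c(4L, 6L),
                     level = c(1L, 3L))
  tr_true <- simulate_labeled_populations(spec, seed = 52)
  panel <- synthetic_panel(600, seed = 52)
  ds <- generate_dataset(tr_true, panel, zero_stutter_model(), coverage = 20,
                         rate = 2e-2, seed = 52)
  calls <- call_genotypes(ds$histograms, zero_stutter_model(), panel)
  m <- assemble_matrix(calls)
  tr <- build_nj_tree(mutation_count_distance(m, min_shared = 50L))
  r <- root_tree(tr, m, group = sprintf("PBL_%02d", 1:4))
  expect_true(ape::is.rooted(r))
  # the later-diverging metastasis group stays together under this rooting
  expect_true(ape::is.monophyletic(r, sprintf("Met_%02d", 1:6)))
})

test_that("PHYLIP export round-trips through ape", {
  m <- rbind(a = c(13L, 14L, 15L), b = c(13L, 15L, 15L), c = c(12L, 15L, 16L))
  colnames(m) <- sprintf("L%d", 1:3)
  d <- mutation_count_distance(m, min_shared = 1L)
  path <- file.path(withr::local_tempdir(), "d.phy")
  write_phylip(d, path)
  lines <- readLines(path)
  expect_match(lines[1], "^\\s+3$")
  expect_length(lines, 4L)
})
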