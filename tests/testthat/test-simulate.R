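# Lineage simulator: benchmark trees, stepwise mutation, dataset bundles.

test_that("benchmark tree has the designed depth, leaf count and determinism", {
  tr <- simulate_benchmark_tree(seed = 21)
  expect_equal(length(tr$tip.label), 32L)
  expect_true(all(tr$leaf.depth.divisions >= 9 * 12))
  expect_true(all(tr$leaf.depth.divisions <= 9 * 15))
  tr2 <- simulate_benchmark_tree(seed = 21)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- simulate_benchmark_tree(seed = 22)
  expect_false(identical(ape::write.tree(tr), ape::write.tree(tr3)))
})

test_that("degenerate and custom branching designs work", {
  tiny <- simulate_benchmark_tree(levels = 1, seed = 1)
  expect_equal(length(tiny$tip.label), 1L)
  wide <- simulate_benchmark_tree(levels = 3, branching = c(3, 2), seed = 2)
  expect_equal(length(wide$tip.label), 6L)
  expect_error(simulate_benchmark_tree(levels = 3, branching = c(0, 2)),
               "branching")
})

test_that("zero mutation rate leaves all genotypes at the reference", {
  tr <- simulate_benchmark_tree(seed = 3)
  panel <- synthetic_panel(50, seed = 3)
  g <- evolve_genotypes(tr, panel, rate = 0, seed = 3)
  expect_true(all(g == matrix(panel$ref_repeat_count, nrow(g), ncol(g),
                              byrow = TRUE)))
})

test_that("per-leaf mutated fraction matches the binomial closed form", {
  # one lineage sampled through 9 levels: each locus mutates ~Binomial(9, mu)
  tr <- simulate_benchmark_tree(levels = 9, branching = 1, seed = 4)
  expect_equal(length(tr$tip.label), 1L)
  panel <- synthetic_panel(20000, seed = 4)
  mu <- 1e-3
  g <- evolve_genotypes(tr, panel, rate = mu, seed = 4)
  frac <- mean(g[1, ] != panel$ref_repeat_count)
  expected <- 1 - (1 - mu)^9          # ~0.00896
  se <- sqrt(expected * (1 - expected) / ncol(g))
  expect_lt(abs(frac - expected), 4 * se)
  # steps are +/-1 (reversals aside, leaves stay within a few units)
  expect_true(all(abs(g[1, ] - panel$ref_repeat_count) <= 9))
  expect_true(all(g >= 1))
})

test_that("mutation counts along a path are Binomial(g, mu)", {
  # chain of 5 levels at a high rate; chi-square against Binomial(5, mu)
  tr <- simulate_benchmark_tree(levels = 5, branching = 1, seed = 6)
  panel <- synthetic_panel(10000, seed = 6)
  mu <- 0.05
  g <- evolve_genotypes(tr, panel, rate = mu, seed = 6)
  # |difference from reference| undercounts mutations only via reversals;
  # compare the zero-mutation class, which is unaffected at leading order
  p0_obs <- mean(g[1, ] == panel$ref_repeat_count)
  p0_theory <- dbinom(0, 5, mu) +
    dbinom(2, 5, mu) * 0.5 +          # +1 then -1 (or -1 then +1) reverts
    dbinom(1, 5, mu) * 0
  expect_lt(abs(p0_obs - p0_theory), 0.01)
})

test_that("labeled populations are sized and placed as specified", {
  spec <- data.frame(label = c("PBL", "Met1", "Met2"),
                     n_cells = c(5L, 4L, 6L),
                     level = c(1L, 3L, 3L))
  tr <- simulate_labeled_populations(spec, seed = 8)
  expect_equal(length(tr$tip.label), 15L)
  lab <- tr$leaf.labels
  expect_equal(as.vector(table(lab)[spec$label]), spec$n_cells)
  # each group is monophyletic in the truth tree
  for (l in spec$label) {
    expect_true(ape::is.monophyletic(tr, names(lab)[lab == l]))
  }
  expect_error(simulate_labeled_populations(spec[1, , drop = FALSE]),
               "2 groups")
})

test_that("generate_dataset composes evolution and stutter sampling", {
  tr <- simulate_benchmark_tree(levels = 3, branching = 2, seed = 9)
  panel <- synthetic_panel(30, seed = 9)
  ds0 <- generate_dataset(tr, panel, zero_stutter_model(), coverage = 25,
                          rate = 5e-3, seed = 9)
  h <- ds0$histograms
  # zero stutter: every cell-locus histogram is a single bin at the truth
  expect_true(all(h$count == 25L))
  key <- paste(h$cell_id, h$locus_id)
  expect_false(anyDuplicated(key) > 0)
  truth <- ds0$truth$genotypes
  expect_true(all(h$repeat_len ==
                    truth[cbind(h$cell_id, h$locus_id)]))
  # zero coverage: no reads at all
  ds_empty <- generate_dataset(tr, panel, zero_stutter_model(), coverage = 0,
                               seed = 9)
  expect_equal(nrow(ds_empty$histograms), 0L)
  # seeded determinism of the full bundle
  ds1 <- generate_dataset(tr, panel, stutter_model(), coverage = 10, seed = 10)
  ds2 <- generate_dataset(tr, panel, stutter_model(), coverage = 10, seed = 10)
  expect_identical(ds1$histograms, ds2$histograms)
  expect_identical(ds1$truth$genotypes, ds2$truth$genotypes)
})

test_that("dataset export writes consistent text artifacts", {
  tr <- simulate_benchmark_tree(levels = 2, branching = 2, seed = 12)
  panel <- synthetic_panel(10, seed = 12)
  ds <- generate_dataset(tr, panel, stutter_model(), coverage = 12, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  h <- data.table::fread(paths[["histograms"]])
  expect_equal(nrow(h), nrow(ds$histograms))
  tre <- ape::read.tree(paths[["tree"]])
  expect_setequal(tre$tip.label, tr$tip.label)
})
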