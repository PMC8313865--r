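# End-to-end benchmark: simulate a nine-level clonal-expansion experiment,
# run the full genotyping + reconstruction + bootstrap pipeline, and score
# the result against the known truth.

#' Estimate the per-locus per-generation mutation rate
#'
#' Mean per-generation genotype-change fraction along the known tree: for
#' every leaf, the fraction of its called pseudo-loci whose repeat value
#' differs from the founder genotype, divided by the leaf's depth in
#' sampling generations, averaged over leaves.
#'
#' @param m called genotype matrix (cells x pseudo-loci).
#' @param root_genotype founder genotype vector over the same columns.
#' @param generations sampling generations from founder to each leaf
#'   (scalar or named vector by cell).
#' @return estimated mutation rate per locus per generation.
#' @export
estimate_mutation_rate <- function(m, root_genotype, generations) {
  if (length(root_genotype) != ncol(m)) {
    stop("root genotype length must match matrix columns")
  }
  gen <- if (length(generations) == 1L) {
    setNames(rep(generations, nrow(m)), rownames(m))
  } else generations
  per_leaf <- vapply(rownames(m), function(cell) {
    sh <- !is.na(m[cell, ]) & !is.na(root_genotype)
    if (!sum(sh)) return(NA_real_)
    mean(m[cell, sh] != root_genotype[sh]) / gen[[cell]]
  }, numeric(1))
  mean(per_leaf, na.rm = TRUE)
}

#' Run the simulated lineage benchmark
#'
#' Simulates a clonal-expansion tree (default: nine sampling levels of
#' 12-15 cell divisions each, 32 sampled cells), evolves a mono-allelic
#' dinucleotide panel under the stepwise mutation model, draws stuttered
#' read histograms, genotypes them, reconstructs the NJ lineage tree from
#' the mutation-count distance matrix, runs the loci-subsampling bootstrap
#' and computes, for every true sampling-level split, the transfer
#' bootstrap expectation over the replicates.  Also reports the estimated
#' mutation rate and the normalized triples distance between the rooted
#' reconstruction and the truth.
#'
#' @param seed integer seed governing the whole run.
#' @param levels,divisions,branching passed to
#'   \code{\link{simulate_benchmark_tree}}.
#' @param n_loci panel size (default 5000 AC loci).
#' @param rate per-generation mutation rate (default 1e-3).
#' @param cycles effective stutter cycles (default 17).
#' @param coverage reads per cell-locus (default 30).
#' @param B bootstrap replicates (default 100).
#' @param keep_fraction loci kept per replicate (default 2/3).
#' @param min_coverage,confidence_threshold genotyping thresholds.
#' @param min_shared minimal shared loci for a defined distance.
#' @return list of class \code{lineage_benchmark}: truth, genotype matrix,
#'   reconstructed trees (unrooted and rooted), TBE table over true splits,
#'   \code{median_tbe_percent}, \code{mutation_rate_estimate},
#'   \code{triples_distance_to_truth}, call-rate and accuracy summaries.
#' @export
run_benchmark <- function(seed = 1L, levels = 9L, divisions = c(12L, 15L),
                          branching = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
                          n_loci = 5000L, rate = 1e-3, cycles = 17L,
                          coverage = 30L, B = 100L, keep_fraction = 2 / 3,
                          min_coverage = 10L, confidence_threshold = 0.05,
                          min_shared = 50L) {
  set_seed_if(seed)
  panel <- synthetic_panel(n_loci)
  truth_tree <- simulate_benchmark_tree(levels = levels,
                                        divisions = divisions,
                                        branching = branching)
  model <- if (cycles > 0L) stutter_model(cycles = cycles) else
    zero_stutter_model()
  dataset <- generate_dataset(truth_tree, panel, model, coverage = coverage,
                              rate = rate)
  calls <- call_genotypes(dataset$histograms, model, panel,
                          min_coverage = min_coverage,
                          confidence_threshold = confidence_threshold)
  m <- assemble_matrix(calls)
  d <- mutation_count_distance(m, min_shared = min_shared)
  tree <- build_nj_tree(d)
  root_geno <- setNames(as.integer(panel$ref_repeat_count), panel$locus_id)
  rooted <- root_tree(tree, m, root_geno[colnames(m)], method = "outgroup",
                      min_shared = min_shared)
  reps <- bootstrap_replicates(m, keep_fraction = keep_fraction, B = B,
                               min_shared = min_shared)
  tbe <- compute_tbe(dataset$truth$tree, reps)
  # genotyping accuracy against the simulated truth
  truth_g <- dataset$truth$genotypes
  acc <- {
    common <- intersect(colnames(m), colnames(truth_g))
    called <- !is.na(m[, common, drop = FALSE])
    ok <- m[, common, drop = FALSE] == truth_g[rownames(m), common]
    sum(ok & called, na.rm = TRUE) / sum(called)
  }
  mu_hat <- estimate_mutation_rate(m, root_geno[colnames(m)],
                                   generations = levels)
  td <- triples_distance(rooted, dataset$truth$tree)
  structure(list(
    panel = panel, truth = dataset$truth, model = model,
    calls = calls, genotypes = m, distance = d,
    tree = tree, rooted_tree = rooted, replicates = length(reps),
    tbe = tbe,
    median_tbe_percent = median(tbe$tbe_percent),
    mutation_rate_estimate = mu_hat,
    genotype_accuracy = acc,
    call_rate = attr(m, "call_rate"),
    triples_distance_to_truth = td,
    parameters = list(seed = seed, levels = levels, divisions = divisions,
                      n_loci = n_loci, rate = rate, cycles = cycles,
                      coverage = coverage, B = B,
                      keep_fraction = keep_fraction)
  ), class = "lineage_benchmark")
}

#' @export
print.lineage_benchmark <- function(x, ...) {
  p <- x$parameters
  cat("Simulated lineage benchmark (seed ", p$seed, ")\n", sep = "")
  cat("  ", p$levels, " sampling levels, ", length(x$truth$tree$tip.label),
      " cells, ", p$n_loci, " loci, rate ", p$rate,
      "/generation, ", p$cycles, " stutter cycles, ", p$coverage,
      "x coverage\n", sep = "")
  cat(sprintf("  call rate            %.3f\n", x$call_rate))
  cat(sprintf("  genotype accuracy    %.4f\n", x$genotype_accuracy))
  cat(sprintf("  mutation rate est.   %.2e (true %.2e)\n",
              x$mutation_rate_estimate, x$parameters$rate))
  cat(sprintf("  median TBE           %.1f%% over %d true splits (%d replicates)\n",
              x$median_tbe_percent, nrow(x$tbe), x$replicates))
  cat(sprintf("  triples distance     %.4f (rooted reconstruction vs truth)\n",
              x$triples_distance_to_truth))
  invisible(x)
}

#' Write a benchmark report as JSON
#'
#' @param bench \code{lineage_benchmark}.
#' @param path output JSON path.
#' @export
write_benchmark_report <- function(bench, path) {
  report <- list(
    parameters = bench$parameters,
    n_cells = length(bench$truth$tree$tip.label),
    replicates = bench$replicates,
    call_rate = bench$call_rate,
    genotype_accuracy = bench$genotype_accuracy,
    mutation_rate_estimate = bench$mutation_rate_estimate,
    median_tbe_percent = bench$median_tbe_percent,
    triples_distance_to_truth = bench$triples_distance_to_truth,
    tbe = bench$tbe[, c("branch_id", "p", "mean_transfer", "tbe_percent")]
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
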