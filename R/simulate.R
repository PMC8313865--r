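# Ground-truth lineage simulation: clonal-expansion sampling trees,
# stepwise STR mutation along edges, and read-histogram generation through
# the stutter model.

#' Synthetic hyper-mutable STR panel
#'
#' Builds a panel of mono-allelic dinucleotide loci with reference repeat
#' counts drawn uniformly from \code{repeat_range} and random flanks, for
#' use in simulation studies.
#'
#' @param n_loci number of loci.
#' @param unit repeat unit (default "AC").
#' @param repeat_range inclusive range of reference repeat counts
#'   (default 11-20, i.e. inside the hyper-mutable dinucleotide class).
#' @param flank_length flank length in nt (default 20).
#' @param seed optional seed.
#' @return panel data.frame as accepted by \code{\link{validate_panel}}.
#' @export
synthetic_panel <- function(n_loci, unit = "AC", repeat_range = c(11L, 20L),
                            flank_length = 20L, seed = NULL) {
  set_seed_if(seed)
  reps <- sample(repeat_range[1]:repeat_range[2], n_loci, replace = TRUE)
  rand_flank <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), flank_length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  validate_panel(data.frame(
    locus_id = sprintf("L%05d", seq_len(n_loci)),
    chrom = "chrX",
    start = 0L,
    end = nchar(unit) * reps,
    unit = unit,
    ref_repeat_count = reps,
    flank_left = rand_flank(n_loci),
    flank_right = rand_flank(n_loci),
    stringsAsFactors = FALSE
  ))
}

#' Simulate a clonal-expansion benchmark tree
#'
#' Emulates an ex vivo single-cell sampling design: starting from a founding
#' cell, lineages are sampled at \code{levels} successive levels, each level
#' separated by a number of cell divisions drawn uniformly from
#' \code{divisions}.  At level \code{k < levels} each lineage founds
#' \code{branching[k]} daughter lineages; cells arriving at the final level
#' are the sampled leaves.  The default branching (binary at levels 1-5,
#' single-lineage continuation afterwards) yields exactly 32 leaves whose
#' divergences are spread across the nine-level design.
#'
#' @param levels number of sampling levels (default 9).
#' @param divisions inclusive range of cell divisions per level
#'   (default c(12, 15)).
#' @param branching integer vector (recycled to \code{levels - 1}) of
#'   daughter lineages founded at each non-final level; all entries >= 1.
#' @param seed optional seed.
#' @return an \code{ape} \code{phylo} tree whose edge lengths are division
#'   counts, with extra components \code{edge.levels} (sampling levels
#'   spanned by each edge) and \code{leaf.depth.divisions}.
#' @export
simulate_benchmark_tree <- function(levels = 9L,
                                    divisions = c(12L, 15L),
                                    branching = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
                                    seed = NULL) {
  set_seed_if(seed)
  if (levels < 1L) stop("levels must be >= 1")
  if (levels > 1L) {
    branching <- rep_len(as.integer(branching), levels - 1L)
    if (any(branching < 1L)) stop("branching must be >= 1 at every level")
  } else branching <- integer(0)
  # lineage: parent key, accumulated divisions and levels since parent node
  active <- list(list(parent = "root", divs = 0L, lvls = 0L))
  edges <- list()   # list of (parent key, child key, divisions, levels)
  n_leaf <- 0L; n_int <- 0L
  for (k in seq_len(levels)) {
    nxt <- list()
    for (lin in active) {
      d <- sample(divisions[1]:divisions[2], 1L)
      divs <- lin$divs + d; lvls <- lin$lvls + 1L
      if (k == levels) {
        n_leaf <- n_leaf + 1L
        key <- sprintf("cell_%03d", n_leaf)
        edges[[length(edges) + 1L]] <- list(lin$parent, key, divs, lvls)
      } else if (branching[k] > 1L) {
        n_int <- n_int + 1L
        key <- sprintf("anc_%03d", n_int)
        edges[[length(edges) + 1L]] <- list(lin$parent, key, divs, lvls)
        for (b in seq_len(branching[k])) {
          nxt[[length(nxt) + 1L]] <- list(parent = key, divs = 0L, lvls = 0L)
        }
      } else {
        nxt[[length(nxt) + 1L]] <- list(parent = lin$parent, divs = divs,
                                        lvls = lvls)
      }
    }
    active <- nxt
  }
  tip_keys <- sprintf("cell_%03d", seq_len(n_leaf))
  node_keys <- c("root", sprintf("anc_%03d", seq_len(n_int)))
  id <- setNames(seq_len(n_leaf + 1L + n_int),
                 c(tip_keys, node_keys))
  edge <- t(vapply(edges, function(e) c(id[[e[[1]]]], id[[e[[2]]]]),
                   numeric(2)))
  tr <- structure(list(edge = edge,
                       edge.length = vapply(edges, function(e) as.numeric(e[[3]]),
                                            numeric(1)),
                       tip.label = tip_keys,
                       Nnode = n_int + 1L),
                  class = "phylo", order = "cladewise")
  tr$edge.levels <- vapply(edges, function(e) as.integer(e[[4]]), integer(1))
  depth <- ape::node.depth.edgelength(tr)
  tr$leaf.depth.divisions <- setNames(depth[seq_len(n_leaf)], tip_keys)
  tr
}

#' Simulate labeled cell populations on a lineage
#'
#' Builds a truth tree in which each labeled population is a clade attached
#' to a backbone lineage at a prescribed divergence level, emulating
#' multi-population sampling designs (e.g. blood versus metastases).
#'
#' @param group_spec data.frame with columns \code{label}, \code{n_cells},
#'   \code{level} (divergence level of the clade, >= 1); at least 2 rows.
#' @param leaf_level sampling level of all leaves (default
#'   \code{max(level) + 3}).
#' @param seed optional seed.
#' @return \code{phylo} tree with \code{edge.levels} and a
#'   \code{leaf.labels} factor (population label per leaf).
#' @export
simulate_labeled_populations <- function(group_spec, leaf_level = NULL,
                                         seed = NULL) {
  set_seed_if(seed)
  stopifnot(all(c("label", "n_cells", "level") %in% names(group_spec)))
  if (nrow(group_spec) < 2L) stop("need at least 2 groups")
  if (is.null(leaf_level)) leaf_level <- max(group_spec$level) + 3L
  if (any(group_spec$level >= leaf_level)) {
    stop("divergence levels must be below leaf_level")
  }
  tip_keys <- character(0); tip_labels <- character(0)
  edges <- list(); n_int <- 0L
  # backbone nodes at each divergence level
  lvls <- sort(unique(group_spec$level))
  node_at <- c("0" = "root")
  prev <- "root"; prev_lvl <- 0L
  for (lv in lvls) {
    n_int <- n_int + 1L
    key <- sprintf("bb_%03d", n_int)
    edges[[length(edges) + 1L]] <- list(prev, key, lv - prev_lvl)
    node_at[as.character(lv)] <- key
    prev <- key; prev_lvl <- lv
  }
  int_keys <- sprintf("bb_%03d", seq_len(n_int))
  for (g in seq_len(nrow(group_spec))) {
    lab <- group_spec$label[g]; n <- group_spec$n_cells[g]
    attach_key <- node_at[as.character(group_spec$level[g])]
    # group ancestor hangs one level below the attachment point
    n_int <- n_int + 1L
    gkey <- sprintf("grp_%03d", n_int)
    int_keys <- c(int_keys, gkey)
    edges[[length(edges) + 1L]] <- list(attach_key, gkey, 1L)
    for (i in seq_len(n)) {
      key <- sprintf("%s_%02d", lab, i)
      tip_keys <- c(tip_keys, key); tip_labels <- c(tip_labels, lab)
      edges[[length(edges) + 1L]] <-
        list(gkey, key, leaf_level - group_spec$level[g] - 1L)
    }
  }
  node_keys <- c("root", int_keys)
  id <- setNames(seq_along(c(tip_keys, node_keys)), c(tip_keys, node_keys))
  edge <- t(vapply(edges, function(e) c(id[[e[[1]]]], id[[e[[2]]]]),
                   numeric(2)))
  tr <- structure(list(edge = edge,
                       edge.length = vapply(edges, function(e) as.numeric(e[[3]]),
                                            numeric(1)),
                       tip.label = tip_keys,
                       Nnode = length(node_keys)),
                  class = "phylo", order = "cladewise")
  tr <- ape::collapse.singles(tr)
  tr$edge.levels <- as.integer(round(tr$edge.length))
  tr$leaf.labels <- setNames(factor(tip_labels), tip_keys)
  tr
}

#' Evolve STR genotypes along a truth tree
#'
#' Stepwise mutation model: along every edge each locus mutates
#' independently; under the default per-sampling-level parameterization an
#' edge spanning \code{g} levels applies the per-generation rate \code{g}
#' times (mutation count ~ Binomial(g, rate)); with
#' \code{per_division = TRUE} each cell division applies
#' \code{rate / mean(divisions per level)} instead.  Each mutation steps the
#' repeat count by -1 or +1 with the probabilities in \code{step_probs};
#' counts are floored at 1 repeat.
#'
#' @param tree truth tree from \code{\link{simulate_benchmark_tree}} or
#'   \code{\link{simulate_labeled_populations}} (needs \code{edge.levels}).
#' @param panel panel data.frame; root genotype = \code{ref_repeat_count}.
#' @param rate per-locus mutation rate per sampling generation
#'   (default 1e-3).
#' @param step_probs probabilities of a -1 / +1 step (must sum to 1).
#' @param per_division apply the rate per cell division instead of per
#'   sampling level.
#' @param seed optional seed.
#' @return integer matrix, leaves x loci (dimnames = cell ids x locus ids).
#' @export
evolve_genotypes <- function(tree, panel, rate = 1e-3,
                             step_probs = c("-1" = 0.5, "+1" = 0.5),
                             per_division = FALSE, seed = NULL) {
  set_seed_if(seed)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (abs(sum(step_probs) - 1) > 1e-12) stop("step_probs must sum to 1")
  if (is.null(tree$edge.levels)) stop("tree lacks edge.levels annotation")
  n_loci <- nrow(panel)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  geno <- vector("list", ntip + tree$Nnode)
  geno[[root]] <- as.integer(panel$ref_repeat_count)
  # preorder traversal (cladewise edge order guarantees parent-first)
  out <- matrix(NA_integer_, ntip, n_loci,
                dimnames = list(tree$tip.label, panel$locus_id))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    g <- if (per_division) {
      trials <- as.integer(round(tree$edge.length[e]))
      p <- rate / mean(12:15)
      list(trials = trials, p = p)
    } else {
      list(trials = tree$edge.levels[e], p = rate)
    }
    gt <- geno[[par]]
    nm <- rbinom(n_loci, g$trials, g$p)
    hit <- which(nm > 0L)
    for (i in hit) {
      for (m in seq_len(nm[i])) {
        step <- sample(c(-1L, 1L), 1L, prob = step_probs)
        gt[i] <- max(1L, gt[i] + step)
      }
    }
    geno[[child]] <- gt
    if (child <= ntip) out[child, ] <- gt
  }
  out
}

#' Generate a simulated dataset (histograms plus truth bundle)
#'
#' Composes genotype evolution and stutter sampling: for every cell-locus
#' pair, \code{coverage} reads are drawn through the slippage walk of the
#' stutter model at the cell's true genotype.
#'
#' @param tree truth tree (with \code{edge.levels}).
#' @param panel panel data.frame.
#' @param model \code{\link{stutter_model}}.
#' @param coverage reads per cell-locus (>= 0).
#' @param rate,per_division,seed passed to \code{\link{evolve_genotypes}}
#'   (the seed also governs read sampling).
#' @param genotypes optional precomputed truth genotype matrix (skips
#'   evolution).
#' @return list with \code{histograms} (data.table: cell_id, locus_id,
#'   repeat_len, count), \code{truth} (list: tree, genotypes, panel),
#'   \code{model}, \code{coverage}.
#' @export
generate_dataset <- function(tree, panel, model, coverage = 30L,
                             rate = 1e-3, per_division = FALSE,
                             genotypes = NULL, seed = NULL) {
  set_seed_if(seed)
  if (coverage < 0) stop("coverage must be >= 0")
  if (is.null(genotypes)) {
    genotypes <- evolve_genotypes(tree, panel, rate = rate,
                                  per_division = per_division)
  }
  cells <- rownames(genotypes)
  hist_dt <- data.table::data.table(cell_id = character(0),
                                    locus_id = character(0),
                                    repeat_len = integer(0),
                                    count = integer(0))
  if (coverage > 0L) {
    units <- panel$unit
    parts <- list()
    for (u in unique(units)) {
      idx <- which(units == u)
      # one batched walk over all reads of all cells at loci with this unit
      tmpl <- rep(as.vector(t(genotypes[, idx, drop = FALSE])),
                  each = coverage)
      lens <- walk_lengths(tmpl, u, model)
      dt <- data.table::data.table(
        cell_id = rep(cells, each = length(idx) * coverage),
        locus_id = rep(rep(panel$locus_id[idx], each = coverage),
                       times = length(cells)),
        repeat_len = as.integer(lens))
      parts[[u]] <- dt[, list(count = .N),
                       by = c("cell_id", "locus_id", "repeat_len")]
    }
    hist_dt <- data.table::rbindlist(parts)
    data.table::setkeyv(hist_dt, c("cell_id", "locus_id", "repeat_len"))
  }
  list(histograms = hist_dt[],
       truth = list(tree = tree, genotypes = genotypes, panel = panel),
       model = model, coverage = as.integer(coverage))
}

#' Write simulated truth and histograms to a directory
#'
#' Emits histogram TSV (cell_id, locus_id, repeat_len, count), truth Newick,
#' truth genotype TSV and, when the tree carries population labels, a labels
#' CSV.
#'
#' @param dataset output of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(histograms = file.path(dir, "histograms.tsv"),
             tree = file.path(dir, "truth_tree.nwk"),
             genotypes = file.path(dir, "truth_genotypes.tsv"))
  data.table::fwrite(dataset$histograms, paths[["histograms"]], sep = "\t")
  ape::write.tree(dataset$truth$tree, paths[["tree"]])
  gm <- data.frame(cell_id = rownames(dataset$truth$genotypes),
                   dataset$truth$genotypes, check.names = FALSE)
  write.table(gm, paths[["genotypes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(dataset$truth$tree$leaf.labels)) {
    paths[["labels"]] <- file.path(dir, "labels.csv")
    lab <- dataset$truth$tree$leaf.labels
    write.table(data.frame(cell_id = names(lab), label = as.character(lab)),
                paths[["labels"]], sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
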