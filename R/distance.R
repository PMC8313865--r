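# Mutation-count distances between cells over shared genotyped pseudo-loci.

#' Mutation-count distance matrix
#'
#' For cells i and j, the raw distance is the number of pseudo-loci
#' genotyped in both cells whose repeat values differ; the normalized
#' distance divides by the number of shared genotyped loci.  Pairs sharing
#' fewer than \code{min_shared} loci are undefined (NA); an error is raised
#' only when the undefined pairs disconnect the cell graph.
#'
#' @param m genotype matrix (cells x pseudo-loci, NA = missing).
#' @param normalize divide by the shared-locus count (default TRUE).
#' @param min_shared minimal shared genotyped loci for a defined distance
#'   (default 50).
#' @return object of class \code{mutation_dist}: list with \code{distance}
#'   (symmetric matrix, zero diagonal), \code{shared} (shared-locus counts)
#'   and \code{normalized}.
#' @export
mutation_count_distance <- function(m, normalize = TRUE, min_shared = 50L) {
  if (nrow(m) < 2L) stop("need at least 2 cells")
  cells <- rownames(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(cells, cells))
  S <- matrix(0L, n, n, dimnames = list(cells, cells))
  obs <- !is.na(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sh <- obs[i, ] & obs[j, ]
      s <- sum(sh)
      S[i, j] <- S[j, i] <- s
      if (s < min_shared) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      d <- sum(m[i, sh] != m[j, sh])
      if (normalize) d <- d / s
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyNA(D)) {
    # connectivity of the defined-distance graph
    adj <- !is.na(D)
    comp <- integer(n); comp[1] <- 1L
    repeat {
      grow <- which(comp == 0L &
                      apply(adj[, comp == 1L, drop = FALSE], 1, any))
      if (!length(grow)) break
      comp[grow] <- 1L
    }
    if (any(comp == 0L)) {
      bad <- which(is.na(D), arr.ind = TRUE)
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      stop("distance graph disconnected; undefined pairs include: ",
           paste(head(paste(cells[bad[, 1]], cells[bad[, 2]], sep = "/"), 5),
                 collapse = ", "))
    }
  }
  structure(list(distance = D, shared = S, normalized = normalize),
            class = "mutation_dist")
}

#' @export
print.mutation_dist <- function(x, ...) {
  cat("mutation_dist over", nrow(x$distance), "cells (",
      if (x$normalized) "normalized" else "raw", "),",
      sum(is.na(x$distance[upper.tri(x$distance)])), "undefined pairs\n")
  invisible(x)
}

#' Median genotype of a cell group
#'
#' Per pseudo-locus, the median of the non-missing group values, using the
#' lower median for even counts; NA where no group cell is genotyped.
#'
#' @param m genotype matrix.
#' @param group character vector of cell ids (rows of \code{m}).
#' @return named integer vector over the matrix columns.
#' @export
median_genotype <- function(m, group) {
  if (!length(group)) stop("group must be non-empty")
  miss <- setdiff(group, rownames(m))
  if (length(miss)) stop("cells not in matrix: ", paste(miss, collapse = ", "))
  sub <- m[group, , drop = FALSE]
  apply(sub, 2, function(v) {
    v <- sort(v[!is.na(v)])
    if (!length(v)) return(NA_integer_)
    v[ceiling(length(v) / 2)]  # lower median for even counts
  })
}

#' Export a distance matrix in square PHYLIP format
#'
#' Lets the matrix be fed to external distance-based tree builders (e.g.
#' FastTree2 run outside R).
#'
#' @param d \code{mutation_dist} or plain symmetric matrix.
#' @param path output path.
#' @export
write_phylip <- function(d, path) {
  D <- if (inherits(d, "mutation_dist")) d$distance else d
  if (anyNA(D)) stop("cannot export a matrix with undefined distances")
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("%5d\n", nrow(D)), file = con)
  for (i in seq_len(nrow(D))) {
    cat(sprintf("%-10s", substr(rownames(D)[i], 1, 10)),
        paste(sprintf("%.6f", D[i, ]), collapse = " "), "\n",
        sep = "", file = con)
  }
  invisible(path)
}
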