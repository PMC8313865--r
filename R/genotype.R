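# Stutter-aware genotype calling.  A histogram is matched against the
# stutter model's predicted distributions for candidate mono-allelic and
# balanced biallelic genotypes; the match statistic is the Pearson
# correlation between observed and predicted frequencies over a common
# support window.  Calls require >= min_coverage reads and correlation
# >= 1 - confidence_threshold (i.e. "correlation above 0.95" at the default
# threshold 0.05).

# score candidate genotypes for one histogram; lens/counts are the observed
# support
score_histogram <- function(lens, counts, model, unit,
                            candidate_window = 2L, biallelic = TRUE) {
  amin <- max(1L, min(lens) - candidate_window)
  amax <- max(lens) + candidate_window
  alleles <- seq.int(amin, amax)
  # support window: observed support united with candidate alleles, padded
  # by one guard bin on each side (keeps vectors non-constant for
  # point-mass cases); predicted mass outside the window is negligible at
  # the cycle counts this model targets
  grid <- seq.int(max(1L, amin - 1L), amax + 1L)
  obs <- numeric(length(grid))
  obs[match(lens, grid)] <- counts
  pred_row <- function(a) {
    p <- predict_histogram(model, a, unit)
    row <- numeric(length(grid))
    hit <- match(as.integer(names(p)), grid)
    ok <- !is.na(hit)
    row[hit[ok]] <- p[ok]
    row
  }
  rows <- vapply(alleles, pred_row, numeric(length(grid)))
  mono_cor <- suppressWarnings(as.vector(cor(obs, rows)))
  mono_cor[is.na(mono_cor)] <- -Inf
  best_mono <- which.max(mono_cor)  # ties -> smaller allele
  out <- list(alleles = alleles[best_mono], correlation = mono_cor[best_mono])
  if (biallelic && length(alleles) > 1L) {
    pairs <- combn(seq_along(alleles), 2L)
    mix <- (rows[, pairs[1, ], drop = FALSE] +
              rows[, pairs[2, ], drop = FALSE]) / 2
    bi_cor <- suppressWarnings(as.vector(cor(obs, mix)))
    bi_cor[is.na(bi_cor)] <- -Inf
    best_bi <- which.max(bi_cor)
    out$bi_alleles <- alleles[pairs[, best_bi]]
    out$bi_correlation <- bi_cor[best_bi]
  }
  out
}

#' Call the genotype of one cell-locus histogram
#'
#' Searches mono-allelic candidates within the observed support +/-
#' \code{candidate_window} and all balanced (50/50) biallelic pairs of those
#' candidates, scoring each by Pearson correlation between the normalized
#' observed histogram and the model-predicted distribution over a shared
#' support window.  The mono-allelic optimum is preferred unless the best
#' biallelic correlation exceeds it by more than \code{biallelic_margin}.
#' No call is made below \code{min_coverage} reads or below correlation
#' \code{1 - confidence_threshold}.
#'
#' @param histogram named numeric vector (names = repeat lengths, values =
#'   read counts) or data.frame with \code{repeat_len}, \code{count}.
#' @param model \code{\link{stutter_model}}.
#' @param unit repeat unit of the locus.
#' @param min_coverage minimal total reads (default 10).
#' @param confidence_threshold maximal confidence = 1 - correlation
#'   (default 0.05).
#' @param candidate_window candidate alleles beyond the observed support
#'   (default 2).
#' @param biallelic_margin correlation advantage required to call a
#'   biallelic genotype (default 0.01).
#' @return list with \code{alleles} (integer vector of length 1 or 2, or
#'   NULL for no-call), \code{confidence}, \code{coverage}, \code{called}.
#' @export
call_locus <- function(histogram, model, unit = "AC", min_coverage = 10L,
                       confidence_threshold = 0.05, candidate_window = 2L,
                       biallelic_margin = 0.01) {
  if (is.data.frame(histogram)) {
    lens <- as.integer(histogram$repeat_len); counts <- histogram$count
  } else {
    lens <- as.integer(names(histogram)); counts <- as.numeric(histogram)
  }
  keep <- counts > 0
  lens <- lens[keep]; counts <- counts[keep]
  if (any(counts < 0)) stop("negative read counts")
  coverage <- sum(counts)
  if (coverage < min_coverage) {
    return(list(alleles = NULL, confidence = NA_real_,
                coverage = as.integer(coverage), called = FALSE,
                reason = "low_coverage"))
  }
  sc <- score_histogram(lens, counts, model, unit,
                        candidate_window = candidate_window)
  alleles <- sc$alleles; corr <- sc$correlation
  if (!is.null(sc$bi_correlation) &&
      sc$bi_correlation > corr + biallelic_margin) {
    alleles <- sort(sc$bi_alleles); corr <- sc$bi_correlation
  }
  confidence <- 1 - corr
  if (!is.finite(confidence) || confidence > confidence_threshold) {
    return(list(alleles = NULL, confidence = confidence,
                coverage = as.integer(coverage), called = FALSE,
                reason = "low_confidence"))
  }
  list(alleles = as.integer(alleles), confidence = confidence,
       coverage = as.integer(coverage), called = TRUE, reason = NA_character_)
}

#' Call genotypes for a whole histogram table
#'
#' Applies \code{\link{call_locus}} to every cell-locus histogram.
#' Identical histograms (same unit and counts) are scored once and the
#' result reused, which makes calling fast at benchmark scale.
#'
#' @param histograms data.table/data.frame (cell_id, locus_id, repeat_len,
#'   count).
#' @param model \code{\link{stutter_model}}.
#' @param panel panel (for the unit of each locus).
#' @inheritParams call_locus
#' @return data.table of calls: cell_id, locus_id, allele1, allele2
#'   (NA for mono-allelic), confidence, coverage, called.
#' @export
call_genotypes <- function(histograms, model, panel, min_coverage = 10L,
                           confidence_threshold = 0.05,
                           candidate_window = 2L, biallelic_margin = 0.01) {
  h <- data.table::as.data.table(histograms)
  unit_of <- setNames(panel$unit, panel$locus_id)
  h$unit <- unit_of[h$locus_id]
  if (anyNA(h$unit)) stop("histograms reference loci absent from panel")
  # serialize each histogram to a key; identical histograms share one call
  agg <- h[, list(key = paste0(unit[1], "|",
                               paste(repeat_len, count, sep = ":",
                                     collapse = ","))),
           by = c("cell_id", "locus_id")]
  uniq <- unique(agg$key)
  # identical histograms are scored once and the result reused
  memo <- new.env(parent = emptyenv())
  for (key in uniq) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    unit <- parts[1]
    bins <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)
    lens <- vapply(bins, function(b) as.integer(b[1]), integer(1))
    counts <- vapply(bins, function(b) as.numeric(b[2]), numeric(1))
    coverage <- sum(counts)
    if (coverage < min_coverage) {
      memo[[key]] <- list(a1 = NA_integer_, a2 = NA_integer_,
                          confidence = NA_real_,
                          coverage = as.integer(coverage), called = FALSE)
      next
    }
    sc <- score_histogram(lens, counts, model, unit,
                          candidate_window = candidate_window)
    alleles <- sc$alleles; corr <- sc$correlation
    if (!is.null(sc$bi_correlation) &&
        sc$bi_correlation > corr + biallelic_margin) {
      alleles <- sort(sc$bi_alleles); corr <- sc$bi_correlation
    }
    confidence <- 1 - corr
    called <- is.finite(confidence) && confidence <= confidence_threshold
    memo[[key]] <- list(
      a1 = if (called) as.integer(alleles[1]) else NA_integer_,
      a2 = if (called && length(alleles) > 1L) as.integer(alleles[2]) else NA_integer_,
      confidence = confidence, coverage = as.integer(coverage),
      called = called)
  }
  res <- lapply(agg$key, function(k) memo[[k]])
  out <- data.table::data.table(
    cell_id = agg$cell_id,
    locus_id = agg$locus_id,
    allele1 = vapply(res, `[[`, integer(1), "a1"),
    allele2 = vapply(res, `[[`, integer(1), "a2"),
    confidence = vapply(res, `[[`, numeric(1), "confidence"),
    coverage = vapply(res, `[[`, integer(1), "coverage"),
    called = vapply(res, `[[`, logical(1), "called"))
  data.table::setkeyv(out, c("cell_id", "locus_id"))
  out[]
}

#' Split biallelic loci into mono-allelic pseudo-loci
#'
#' Pools allele values per locus across cells and partitions them into two
#' clusters at the largest gap.  If the cluster centers are separated by
#' more than \code{min_separation} repeat units, the locus is emitted as two
#' pseudo-locus columns (suffixes \code{.1}/\code{.2}) with each cell's
#' alleles assigned to the nearer center; otherwise the locus is kept as a
#' single column holding the lower allele (flagged low-heterogeneity --
#' such loci still contribute information, at the price of inflated
#' terminal branch lengths).
#'
#' @param calls calls table from \code{\link{call_genotypes}}.
#' @param min_separation minimal cluster-center separation, in repeat units,
#'   to split (default 3; "more than" is strict).
#' @param cells optional character vector fixing the row universe.
#' @return integer genotype matrix (cells x pseudo-loci) with NA for
#'   missing; attributes \code{"source_locus"} (named vector),
#'   \code{"low_heterogeneity"} (character vector of unsplit biallelic
#'   loci) and \code{"conflicts"} (cell-locus pairs dropped because both
#'   alleles fell nearer one center).
#' @export
split_biallelic <- function(calls, min_separation = 3, cells = NULL) {
  ct <- data.table::as.data.table(calls)
  ct <- ct[ct$called == TRUE]
  if (is.null(cells)) cells <- sort(unique(ct$cell_id))
  loci <- sort(unique(ct$locus_id))
  cols <- list(); src <- character(0)
  low_het <- character(0); conflicts <- character(0)
  for (loc in loci) {
    sub <- ct[ct$locus_id == loc]
    vals <- c(sub$allele1, sub$allele2)
    vals <- vals[!is.na(vals)]
    uv <- sort(unique(vals))
    two_cluster <- FALSE
    if (length(uv) > 1L) {
      gaps <- diff(uv)
      cut <- which.max(gaps)  # first largest gap
      lo <- uv[seq_len(cut)]; hi <- uv[-seq_len(cut)]
      c1 <- mean(vals[vals %in% lo]); c2 <- mean(vals[vals %in% hi])
      two_cluster <- (c2 - c1) > min_separation
    }
    any_biallelic <- any(!is.na(sub$allele2))
    if (two_cluster) {
      col1 <- setNames(rep(NA_integer_, length(cells)), cells)
      col2 <- col1
      for (r in seq_len(nrow(sub))) {
        al <- c(sub$allele1[r], sub$allele2[r])
        al <- al[!is.na(al)]
        near <- ifelse(abs(al - c1) <= abs(al - c2), 1L, 2L)
        if (length(al) == 2L && near[1] == near[2]) {
          conflicts <- c(conflicts, paste0(sub$cell_id[r], "/", loc))
          next
        }
        if (any(near == 1L)) col1[sub$cell_id[r]] <- al[near == 1L][1]
        if (any(near == 2L)) col2[sub$cell_id[r]] <- al[near == 2L][1]
      }
      cols[[paste0(loc, ".1")]] <- col1
      cols[[paste0(loc, ".2")]] <- col2
      src <- c(src, setNames(c(loc, loc), paste0(loc, c(".1", ".2"))))
    } else {
      col <- setNames(rep(NA_integer_, length(cells)), cells)
      lower <- ifelse(is.na(sub$allele2), sub$allele1,
                      pmin(sub$allele1, sub$allele2))
      col[sub$cell_id] <- lower
      cols[[loc]] <- col
      src <- c(src, setNames(loc, loc))
      if (any_biallelic) low_het <- c(low_het, loc)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(NA_integer_, length(cells), 0, dimnames = list(cells, NULL))
  rownames(m) <- cells
  attr(m, "source_locus") <- src
  attr(m, "low_heterogeneity") <- low_het
  attr(m, "conflicts") <- conflicts
  m
}

#' Assemble the genotype matrix from calls
#'
#' Wraps \code{\link{split_biallelic}} and adds call-rate bookkeeping over
#' the full cell x locus index (including cells/loci with no call at all).
#'
#' @inheritParams split_biallelic
#' @param loci optional character vector fixing the source-locus universe
#'   for the call-rate report.
#' @return genotype matrix as in \code{\link{split_biallelic}}, with an
#'   additional \code{"call_rate"} attribute (overall fraction of called
#'   cell-locus pairs) and \code{"cell_call_rate"} named vector.
#' @export
assemble_matrix <- function(calls, min_separation = 3, cells = NULL,
                            loci = NULL) {
  ct <- data.table::as.data.table(calls)
  if (is.null(cells)) cells <- sort(unique(ct$cell_id))
  if (is.null(loci)) loci <- sort(unique(ct$locus_id))
  m <- split_biallelic(ct, min_separation = min_separation, cells = cells)
  called <- ct[ct$called == TRUE]
  attr(m, "call_rate") <- nrow(called) / (length(cells) * length(loci))
  per_cell <- setNames(rep(0, length(cells)), cells)
  if (nrow(called)) {
    tab <- table(called$cell_id) / length(loci)
    per_cell[names(tab)] <- as.numeric(tab)
  }
  attr(m, "cell_call_rate") <- per_cell
  m
}

#' Write a genotype matrix as TSV
#'
#' @param m genotype matrix.
#' @param path output path ("NA" marks missing entries).
#' @export
write_genotype_matrix <- function(m, path) {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
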