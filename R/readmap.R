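# Enumerated STR-variant reference and read -> repeat-length histogram
# conversion.  Instead of aligning against the genome, every plausible
# repeat-length variant of every panel locus is enumerated; assigning a read
# to a variant is then equivalent to assigning it a repeat length.  Reads
# are located by exact (optionally 1-mismatch) matches of short anchor
# k-mers taken from the innermost flank bases.

#' Build the enumerated STR-variant reference
#'
#' For each locus, enumerates variant sequences \code{flank_left +
#' unit x k + flank_right} for repeat counts within
#' \code{ref_repeat_count +/- window} (floored at 1), and records the two
#' anchor k-mers (last \code{anchor_length} bases of the left flank, first
#' \code{anchor_length} bases of the right flank).  Anchors shared between
#' loci are flagged ambiguous and those loci are excluded from
#' classification.
#'
#' @param panel validated panel with flank sequences.
#' @param window repeat-count window around the reference count (default 10).
#' @param anchor_length anchor k-mer length (default 15).
#' @return object of class \code{str_variant_reference}.
#' @export
build_variant_reference <- function(panel, window = 10L, anchor_length = 15L) {
  panel <- validate_panel(panel)
  if (!all(c("flank_left", "flank_right") %in% names(panel))) {
    stop("panel lacks flank sequences")
  }
  if (any(nchar(panel$flank_left) < anchor_length) ||
      any(nchar(panel$flank_right) < anchor_length)) {
    stop("flanks shorter than anchor_length (", anchor_length, ")")
  }
  left <- substr(panel$flank_left,
                 nchar(panel$flank_left) - anchor_length + 1L,
                 nchar(panel$flank_left))
  right <- substr(panel$flank_right, 1L, anchor_length)
  dup <- left %in% left[duplicated(left)] | right %in% right[duplicated(right)]
  variants <- lapply(seq_len(nrow(panel)), function(i) {
    ks <- seq.int(max(1L, panel$ref_repeat_count[i] - window),
                  panel$ref_repeat_count[i] + window)
    data.frame(repeat_count = ks,
               sequence = paste0(panel$flank_left[i],
                                 strrep(panel$unit[i], ks),
                                 panel$flank_right[i]),
               stringsAsFactors = FALSE)
  })
  names(variants) <- panel$locus_id
  structure(list(panel = panel,
                 anchor_length = as.integer(anchor_length),
                 window = as.integer(window),
                 left_anchor = setNames(left, panel$locus_id),
                 right_anchor = setNames(right, panel$locus_id),
                 ambiguous = setNames(dup, panel$locus_id),
                 variants = variants),
            class = "str_variant_reference")
}

#' @export
print.str_variant_reference <- function(x, ...) {
  cat("str_variant_reference:", nrow(x$panel), "loci, window +/-", x$window,
      "repeats,", sum(x$ambiguous), "ambiguous\n")
  invisible(x)
}

#' Write the variant reference as FASTA
#'
#' @param ref \code{str_variant_reference}.
#' @param path output FASTA path; records are named
#'   \code{<locus_id>|<repeat_count>}.
#' @export
write_variant_fasta <- function(ref, path) {
  seqs <- unlist(lapply(names(ref$variants), function(loc) {
    v <- ref$variants[[loc]]
    setNames(v$sequence, paste0(loc, "|", v$repeat_count))
  }))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

# locate `anchor` in `read` allowing up to max_mismatch substitutions;
# returns 1-based start or NA
find_anchor <- function(read, anchor, max_mismatch = 0L) {
  pos <- regexpr(anchor, read, fixed = TRUE)
  if (pos > 0L) return(as.integer(pos))
  if (max_mismatch < 1L) return(NA_integer_)
  n <- nchar(read); k <- nchar(anchor)
  if (n < k) return(NA_integer_)
  rb <- strsplit(read, "")[[1]]
  ab <- strsplit(anchor, "")[[1]]
  for (s in seq_len(n - k + 1L)) {
    if (sum(rb[s:(s + k - 1L)] != ab) <= max_mismatch) return(s)
  }
  NA_integer_
}

#' Classify one read against the variant reference
#'
#' Finds the left and right anchors (exact k-mer match; with
#' \code{max_mismatch = 1} a single-substitution fallback is allowed) and
#' converts the inter-anchor span to a repeat length, provided the span is a
#' whole number of units and is unit-periodic.
#'
#' @param read DNA string.
#' @param ref \code{str_variant_reference}.
#' @param max_mismatch per-anchor mismatch allowance (0 = strict, default 0).
#' @return list with \code{locus_id}, \code{repeat_len} (both NA when
#'   unmapped) and \code{reason} for unmapped reads.
#' @export
classify_read <- function(read, ref, max_mismatch = 0L) {
  read <- toupper(read)
  for (loc in names(ref$left_anchor)) {
    if (ref$ambiguous[[loc]]) next
    lp <- find_anchor(read, ref$left_anchor[[loc]], max_mismatch)
    if (is.na(lp)) next
    rp <- find_anchor(read, ref$right_anchor[[loc]], max_mismatch)
    if (is.na(rp)) {
      return(list(locus_id = NA_character_, repeat_len = NA_integer_,
                  reason = "right_anchor_missing"))
    }
    span_start <- lp + ref$anchor_length
    if (rp <= span_start) {
      return(list(locus_id = NA_character_, repeat_len = NA_integer_,
                  reason = "anchors_overlap"))
    }
    span <- substr(read, span_start, rp - 1L)
    unit <- ref$panel$unit[ref$panel$locus_id == loc]
    ulen <- nchar(unit)
    if (nchar(span) %% ulen != 0L) {
      return(list(locus_id = NA_character_, repeat_len = NA_integer_,
                  reason = "non_integer_span"))
    }
    k <- nchar(span) %/% ulen
    if (strrep(unit, k) != span) {
      return(list(locus_id = NA_character_, repeat_len = NA_integer_,
                  reason = "not_unit_periodic"))
    }
    return(list(locus_id = loc, repeat_len = as.integer(k), reason = NA_character_))
  }
  list(locus_id = NA_character_, repeat_len = NA_integer_,
       reason = "no_anchor")
}

#' Convert reads to per-cell-locus repeat-length histograms
#'
#' Reads may be given as a FASTQ file path or a named character vector; the
#' cell id is taken from the read name prefix before the first ":".
#'
#' @param reads FASTQ path or named character vector of read sequences.
#' @param ref \code{str_variant_reference}.
#' @param max_mismatch per-anchor mismatch allowance.
#' @return data.table (cell_id, locus_id, repeat_len, count) with attributes
#'   \code{"n_reads"}, \code{"n_mapped"} and \code{"mapped_fraction"} (per
#'   cell).
#' @export
build_histograms <- function(reads, ref, max_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    dss <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- setNames(as.character(dss), names(dss))
  }
  if (is.null(names(reads))) stop("reads must carry cell ids in their names")
  cell <- sub(":.*$", "", sub(" .*$", "", names(reads)))
  res <- lapply(unname(reads), classify_read, ref = ref,
                max_mismatch = max_mismatch)
  dt <- data.table::data.table(
    cell_id = cell,
    locus_id = vapply(res, `[[`, character(1), "locus_id"),
    repeat_len = vapply(res, `[[`, integer(1), "repeat_len"))
  mapped <- dt[!is.na(dt$locus_id)]
  out <- mapped[, list(count = .N), by = c("cell_id", "locus_id", "repeat_len")]
  data.table::setkeyv(out, c("cell_id", "locus_id", "repeat_len"))
  mf <- dt[, list(mapped_fraction = mean(!is.na(locus_id))), by = "cell_id"]
  attr(out, "n_reads") <- length(reads)
  attr(out, "n_mapped") <- nrow(mapped)
  attr(out, "mapped_fraction") <- mf
  out[]
}

#' Simulate merged reads (FASTQ) from histograms
#'
#' Inverse of \code{\link{build_histograms}} for testing round-trips: each
#' histogram entry yields \code{count} identical reads \code{flank_left +
#' unit x repeat_len + flank_right}, named \code{<cell_id>:<locus_id>:<i>}.
#'
#' @param histograms data.table (cell_id, locus_id, repeat_len, count).
#' @param panel panel with flanks.
#' @param path optional FASTQ output path; when NULL a named character
#'   vector is returned.
#' @return named character vector of reads (invisibly when written).
#' @export
simulate_reads <- function(histograms, panel, path = NULL) {
  h <- data.table::as.data.table(histograms)
  panel_idx <- match(h$locus_id, panel$locus_id)
  if (anyNA(panel_idx)) stop("histograms reference loci absent from panel")
  seqs <- paste0(panel$flank_left[panel_idx],
                 strrep(panel$unit[panel_idx], h$repeat_len),
                 panel$flank_right[panel_idx])
  reads <- rep(seqs, h$count)
  ids <- paste0(rep(h$cell_id, h$count), ":", rep(h$locus_id, h$count))
  ids <- paste0(ids, ":", stats::ave(seq_along(ids), ids, FUN = seq_along))
  names(reads) <- ids
  if (!is.null(path)) {
    dss <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(dss)))
    qdss <- Biostrings::QualityScaledDNAStringSet(dss, q)
    Biostrings::writeQualityScaledXStringSet(qdss, filepath = path)
    return(invisible(reads))
  }
  reads
}

#' Subsample histograms to a lower coverage
#'
#' Per cell-locus pair, draws reads without replacement down to the target
#' (either an absolute \code{target_coverage} or a \code{fraction} of the
#' available reads, rounded to nearest); pairs already at or below the
#' target are unchanged.
#'
#' @param histograms data.table (cell_id, locus_id, repeat_len, count).
#' @param target_coverage absolute reads per cell-locus.
#' @param fraction fraction of available reads (exactly one of the two must
#'   be given).
#' @param seed optional seed.
#' @return subsampled histograms data.table.
#' @export
subsample_histograms <- function(histograms, target_coverage = NULL,
                                 fraction = NULL, seed = NULL) {
  set_seed_if(seed)
  if (is.null(target_coverage) == is.null(fraction)) {
    stop("give exactly one of target_coverage or fraction")
  }
  h <- data.table::as.data.table(histograms)
  sub_one <- function(repeat_len, count) {
    tot <- sum(count)
    tgt <- if (!is.null(target_coverage)) min(tot, target_coverage) else
      round(fraction * tot)
    if (tgt >= tot) return(list(repeat_len = repeat_len, count = count))
    drawn <- sample(rep(repeat_len, count), tgt)
    tab <- table(factor(drawn, levels = repeat_len))
    keep <- tab > 0
    list(repeat_len = repeat_len[keep], count = as.integer(tab[keep]))
  }
  out <- h[, sub_one(repeat_len, count), by = c("cell_id", "locus_id")]
  data.table::setkeyv(out, c("cell_id", "locus_id", "repeat_len"))
  out[]
}
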