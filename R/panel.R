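# Duplex-MIP panel design: hyper-mutable STR locus selection, amplicon
# filters, precursor assembly and in-silico MlyI digestion.

# Constant adapter/backbone elements of a duplex-MIP precursor.  The two
# adapters each contain exactly one MlyI recognition site (GAGTC read on the
# synthesized strand for the forward adapter, GACTC -- i.e. a bottom-strand
# GAGTC -- for the reverse adapter) positioned so that the blunt cut
# GAGTC(N5) releases the adapters exactly at their boundaries.
MLY1_F   <- "GTCTATGAGTGTGGAGTCGTTGC"
MLY1_R   <- "CTAGCTTCCTGATGAGTCCGATG"
BACKBONE <- "AGATCGGAAGAGCACACGTCTGAACTCTTTCCCTACACGACGCTCTTCCGATCT"

#' Adapter and backbone constants of the duplex-MIP precursor
#'
#' @return named list with elements \code{mly1_f}, \code{mly1_r},
#'   \code{backbone}.
#' @export
mip_constants <- function() {
  list(mly1_f = MLY1_F, mly1_r = MLY1_R, backbone = BACKBONE)
}

#' Read an STR panel table
#'
#' Loads a tab-separated locus table with columns \code{locus_id},
#' \code{chrom}, \code{start}, \code{end} (0-based half-open), \code{unit},
#' \code{ref_repeat_count}, \code{flank_left}, \code{flank_right} and
#' validates it with \code{\link{validate_panel}}.
#'
#' @param path path to a TSV file.
#' @return a validated panel \code{data.frame}.
#' @export
read_panel <- function(path) {
  panel <- read.delim(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Validate an STR panel table
#'
#' Checks required columns, interval arithmetic (\code{end - start} must
#' equal \code{nchar(unit) * ref_repeat_count} when coordinates are present)
#' and that repeat units are minimal (no "ACAC"-style units).
#'
#' @param panel data.frame of loci.
#' @return the panel, invisibly validated (with upper-cased sequences).
#' @export
validate_panel <- function(panel) {
  req <- c("locus_id", "unit", "ref_repeat_count")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$locus_id)) stop("duplicate locus_id values in panel")
  panel$unit <- toupper(panel$unit)
  bad <- !grepl("^[ACGT]+$", panel$unit) |
    !vapply(panel$unit, is_minimal_unit, logical(1))
  if (any(bad)) {
    stop("malformed repeat unit for loci: ",
         paste(panel$locus_id[bad], collapse = ", "))
  }
  if (any(panel$ref_repeat_count < 1)) stop("ref_repeat_count must be >= 1")
  if (all(c("start", "end") %in% names(panel))) {
    span <- panel$end - panel$start
    expect <- nchar(panel$unit) * panel$ref_repeat_count
    bad <- !is.na(span) & span != expect
    if (any(bad)) {
      stop("end - start != unit length x repeat count for loci: ",
           paste(panel$locus_id[bad], collapse = ", "))
    }
  }
  for (fl in c("flank_left", "flank_right")) {
    if (fl %in% names(panel)) panel[[fl]] <- toupper(panel[[fl]])
  }
  panel
}

#' Select hyper-mutable STR loci
#'
#' Keeps AC- and AG-type dinucleotide loci longer than 10 repeats and A- and
#' G-type mononucleotide loci longer than 6 repeats; every other unit type is
#' dropped.  Unit classes are matched after reduction to the canonical
#' rotation; with \code{unify_revcomp = TRUE} reverse-complement classes are
#' pooled (GT counts as AC, C as G, T as A).
#'
#' @param panel validated panel data.frame.
#' @param unify_revcomp pool reverse-complement unit classes (default TRUE).
#' @return the subset of \code{panel} passing the mutability filter.
#' @export
select_hypermutable_loci <- function(panel, unify_revcomp = TRUE) {
  panel <- validate_panel(panel)
  cls <- canonical_unit(panel$unit, unify_revcomp = unify_revcomp)
  di_units <- canonical_unit(c("AC", "AG"), unify_revcomp = unify_revcomp)
  mono_units <- canonical_unit(c("A", "G"), unify_revcomp = unify_revcomp)
  keep <- (cls %in% di_units & panel$ref_repeat_count > 10) |
    (cls %in% mono_units & panel$ref_repeat_count > 6)
  panel[keep, , drop = FALSE]
}

#' Check a candidate amplicon
#'
#' An amplicon fails if it contains the TTAA motif anywhere (incompatible
#' with the downstream WGA chemistry) or if its length is outside
#' \code{target_length +/- tol}.
#'
#' @param sequence uppercase DNA string (N allowed).
#' @param target_length target amplicon size in bp (default 150).
#' @param tol allowed deviation from \code{target_length} (default 30).
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector among "TTAA", "length").
#' @export
check_amplicon <- function(sequence, target_length = 150L, tol = 30L) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("amplicon contains non-ACGTN characters")
  }
  reasons <- character(0)
  if (grepl("TTAA", sequence, fixed = TRUE)) reasons <- c(reasons, "TTAA")
  if (abs(nchar(sequence) - target_length) > tol) reasons <- c(reasons, "length")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# melting-temperature proxy: Wallace rule 2(A+T) + 4(G+C)
wallace_tm <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  gc <- sum(b %in% c("G", "C"))
  2 * (length(b) - gc) + 4 * gc
}

has_homopolymer <- function(seq, len = 5L) {
  grepl(paste0("(A{", len, "}|C{", len, "}|G{", len, "}|T{", len, "})"), seq)
}

#' Choose targeting arms from locus flanks
#'
#' Heuristic arm picker: the forward arm is taken from the 3' end of the
#' left flank and the reverse arm from the 5' start of the right flank.
#' Candidate lengths 18-25 nt are scanned (shortest first) and the first
#' candidate with GC content in \code{gc_range}, no homopolymer run of 5+
#' and Wallace-rule melting temperature (2(A+T)+4(G+C)) inside
#' \code{tm_range} is kept; arms containing an MlyI recognition word are
#' skipped so the assembled precursor stays digestible at the adapters only.
#'
#' @param locus one-row panel data.frame with \code{flank_left} and
#'   \code{flank_right}.
#' @param arm_lengths integer vector of candidate arm lengths.
#' @param gc_range allowed GC fraction range.
#' @param tm_range allowed Wallace-rule temperature range.
#' @return list with \code{fw_arm} and \code{rv_arm}.
#' @export
design_arms <- function(locus, arm_lengths = 18:25, gc_range = c(0.3, 0.7),
                        tm_range = c(46, 82)) {
  pick <- function(flank, side) {
    for (l in arm_lengths) {
      if (nchar(flank) < l) next
      cand <- if (side == "left") {
        substr(flank, nchar(flank) - l + 1L, nchar(flank))
      } else {
        substr(flank, 1L, l)
      }
      gc <- sum(strsplit(cand, "")[[1]] %in% c("G", "C")) / l
      if (gc < gc_range[1] || gc > gc_range[2]) next
      if (has_homopolymer(cand)) next
      tm <- wallace_tm(cand)
      if (tm < tm_range[1] || tm > tm_range[2]) next
      if (count_matches("GAGTC", cand) + count_matches("GACTC", cand) > 0) next
      return(cand)
    }
    stop("no acceptable ", side, " arm for locus ", locus$locus_id)
  }
  list(fw_arm = pick(locus$flank_left, "left"),
       rv_arm = pick(locus$flank_right, "right"))
}

#' Assemble a duplex-MIP precursor
#'
#' Concatenates, 5' to 3': Mly1_F adapter, forward arm, 3-nt UMI, backbone,
#' 3-nt UMI, reverse-complemented reverse arm, reverse-complemented Mly1_R
#' adapter.  The assembly is rejected if it exceeds 150 nt (synthesis limit)
#' or if any MlyI recognition word (GAGTC/GACTC on either strand) occurs
#' outside the two intended adapter-internal sites.
#'
#' @param fw_arm,rv_arm targeting arm sequences (genomic orientation).
#' @param umi_length length of each randomized UMI stretch (default 3).
#' @param max_length synthesis length limit (default 150).
#' @return object of class \code{mip_precursor}: list with \code{fw_arm},
#'   \code{rv_arm}, \code{full_sequence}, \code{active_sequence}.
#' @export
assemble_precursor <- function(fw_arm, rv_arm, umi_length = 3L,
                               max_length = 150L) {
  fw_arm <- toupper(fw_arm); rv_arm <- toupper(rv_arm)
  for (arm in c(fw_arm, rv_arm)) {
    if (!grepl("^[ACGT]+$", arm)) stop("arm is not a plain DNA string")
    if (count_matches("GAGTC", arm) + count_matches("GACTC", arm) > 0) {
      stop("arm contains an MlyI recognition site (GAGTC/GACTC)")
    }
  }
  umi <- strrep("N", umi_length)
  full <- paste0(MLY1_F, fw_arm, umi, BACKBONE, umi, revcomp(rv_arm),
                 revcomp(MLY1_R))
  if (nchar(full) > max_length) {
    stop("assembled precursor is ", nchar(full), " nt, longer than ",
         max_length, " nt")
  }
  sites <- sort(c(match_positions("GAGTC", full), match_positions("GACTC", full)))
  expected <- c(14L, nchar(full) - 17L)  # inside Mly1_F / revcomp(Mly1_R)
  if (!identical(sites, expected)) {
    stop("precursor harbors MlyI recognition sites outside the adapters")
  }
  structure(list(fw_arm = fw_arm, rv_arm = rv_arm, full_sequence = full,
                 active_sequence = digest_sequence(full)),
            class = "mip_precursor")
}

# blunt MlyI cleavage of one precursor sequence: GAGTC(N5) cutting inward
# from both terminal recognition sites
digest_sequence <- function(full) {
  g <- match_positions("GAGTC", full)
  c5 <- match_positions("GACTC", full)
  if (!length(g) || !length(c5)) {
    stop("precursor lacks the terminal MlyI adapter sites")
  }
  left_cut <- g[1] + 4L + 5L            # last base removed on the left
  right_cut <- c5[length(c5)] - 5L      # first base removed on the right
  if (left_cut >= right_cut) stop("MlyI cut sites overlap; malformed precursor")
  substr(full, left_cut + 1L, right_cut - 1L)
}

#' Digest a precursor to its active MIP
#'
#' Simulates MlyI digestion (blunt cut 5 nt downstream of each terminal
#' GAGTC recognition site, cutting inward), removing both adapter constants.
#' A 150-nt precursor yields a ~105-nt active MIP.
#'
#' @param p a \code{mip_precursor} or a raw precursor DNA string.
#' @return the active (post-digestion) sequence.
#' @export
digest_precursor <- function(p) {
  full <- if (inherits(p, "mip_precursor")) p$full_sequence else toupper(p)
  digest_sequence(full)
}

#' Design a duplex-MIP oligo pool for a panel
#'
#' Runs the mutability filter, picks arms for each retained locus, assembles
#' and validates precursors, and drops loci whose target amplicon (left
#' flank + reference repeat tract + right flank) fails
#' \code{\link{check_amplicon}} or whose arms cannot be chosen.
#'
#' @param panel validated panel with flank sequences.
#' @param tol amplicon length tolerance passed to \code{check_amplicon}.
#' @param unify_revcomp passed to \code{select_hypermutable_loci}.
#' @return data.frame with locus_id, arms, full and active sequences;
#'   attribute \code{"rejected"} records dropped loci and reasons.
#' @export
design_panel <- function(panel, tol = 30L, unify_revcomp = TRUE) {
  panel <- select_hypermutable_loci(panel, unify_revcomp = unify_revcomp)
  if (!all(c("flank_left", "flank_right") %in% names(panel))) {
    stop("panel lacks flank sequences needed for arm design")
  }
  rows <- list(); rejected <- list()
  for (i in seq_len(nrow(panel))) {
    loc <- panel[i, ]
    amplicon <- paste0(loc$flank_left, strrep(loc$unit, loc$ref_repeat_count),
                       loc$flank_right)
    chk <- check_amplicon(amplicon, tol = tol)
    if (!chk$pass) {
      rejected[[loc$locus_id]] <- paste(chk$reasons, collapse = ",")
      next
    }
    res <- tryCatch({
      arms <- design_arms(loc)
      p <- assemble_precursor(arms$fw_arm, arms$rv_arm)
      data.frame(locus_id = loc$locus_id, fw_arm = p$fw_arm,
                 rv_arm = p$rv_arm, full_sequence = p$full_sequence,
                 active_sequence = p$active_sequence,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) rejected[[loc$locus_id]] <- res else rows[[loc$locus_id]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), fw_arm = character(0),
               rv_arm = character(0), full_sequence = character(0),
               active_sequence = character(0))
  rownames(out) <- NULL
  attr(out, "rejected") <- unlist(rejected)
  out
}

#' Write an oligo pool as FASTA
#'
#' @param pool data.frame from \code{\link{design_panel}}.
#' @param path output FASTA path.
#' @param what which sequence column to write.
#' @export
write_oligo_pool <- function(pool, path, what = c("full_sequence",
                                                  "active_sequence")) {
  what <- match.arg(what)
  seqs <- Biostrings::DNAStringSet(pool[[what]])
  names(seqs) <- pool$locus_id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
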