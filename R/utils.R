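#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all rotations of a repeat unit
unit_rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(unit, k + 1L, n), substr(unit, 1L, k))
  }, character(1))
}

#' Canonical form of an STR repeat unit
#'
#' Reduces a repeat unit to its lexicographically minimal rotation; when
#' \code{unify_revcomp} is \code{TRUE} (the default) the reverse-complement
#' unit is pooled into the same class, so e.g. GT and AC share the canonical
#' form "AC".
#'
#' @param unit character vector of repeat units (e.g. "AC", "GT").
#' @param unify_revcomp also pool reverse-complement units into one class.
#' @return character vector of canonical units.
#' @export
canonical_unit <- function(unit, unify_revcomp = TRUE) {
  vapply(unit, function(u) {
    u <- toupper(u)
    if (!grepl("^[ACGT]+$", u)) {
      stop("malformed repeat unit: ", u, call. = FALSE)
    }
    cands <- unit_rotations(u)
    if (unify_revcomp) cands <- c(cands, unit_rotations(revcomp(u)))
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if unit is already its own minimal rotation and not a multiple of a
# shorter unit (e.g. "ACAC" is rejected)
is_minimal_unit <- function(unit) {
  n <- nchar(unit)
  for (k in seq_len(n - 1)) {
    if (n %% k == 0 && strrep(substr(unit, 1, k), n / k) == unit) return(FALSE)
  }
  unit == min(unit_rotations(unit))
}

# count fixed-pattern occurrences (possibly overlapping) in a string
count_matches <- function(pattern, x) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# positions (1-based starts) of fixed-pattern occurrences
match_positions <- function(pattern, x) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# seed guard used by every stochastic entry point
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
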