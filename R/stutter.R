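# PCR amplification stutter as a per-cycle slippage Markov chain on repeat
# length.  Each amplification cycle a molecule of length L loses one repeat
# unit with probability slip_down(unit, L), gains one with slip_up(unit, L),
# and is copied faithfully otherwise; length 1 is an absorbing floor for
# downward slippage.  A sequenced read is modelled as an independent
# C-cycle walk from the template allele ("equivalent to C cycles of
# amplification"; duplex-MIP libraries behave like C in the 15-20 range).

#' Default per-cycle slippage probabilities
#'
#' Slippage grows logistically with repeat length and is unit-class
#' specific: mononucleotide repeats are noisier than dinucleotide (and
#' longer-unit) repeats.  Downward slippage dominates upward slippage by the
#' factor \code{up_ratio}.  These defaults give, at 17 effective cycles,
#' roughly 5-10\% single-unit stutter for a 13-repeat dinucleotide locus --
#' the regime typical of MIP capture libraries.
#'
#' @param unit repeat unit string (only its length is used).
#' @param repeat_length integer vector of repeat lengths.
#' @return numeric vector of per-cycle probabilities.
#' @name slip_defaults
NULL

#' @rdname slip_defaults
#' @export
default_slip_down <- function(unit, repeat_length) {
  if (nchar(unit) == 1L) {
    p <- 0.04 / (1 + exp(-(repeat_length - 12) / 3))
  } else {
    p <- 0.02 / (1 + exp(-(repeat_length - 18) / 4))
  }
  p[repeat_length <= 1L] <- 0
  p
}

#' @rdname slip_defaults
#' @export
default_slip_up <- function(unit, repeat_length, up_ratio = 0.3) {
  d <- if (nchar(unit) == 1L) {
    0.04 / (1 + exp(-(repeat_length - 12) / 3))
  } else {
    0.02 / (1 + exp(-(repeat_length - 18) / 4))
  }
  up_ratio * d
}

#' Construct a stutter model
#'
#' @param cycles effective number of amplification cycles (non-negative
#'   integer; MIP libraries are typically 15-20, default 17).
#' @param slip_down,slip_up vectorized functions \code{(unit,
#'   repeat_length) -> per-cycle probability}.
#' @return object of class \code{stutter_model}.
#' @export
stutter_model <- function(cycles = 17L, slip_down = default_slip_down,
                          slip_up = default_slip_up) {
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 0L) stop("cycles must be a non-negative integer")
  m <- structure(list(cycles = cycles, slip_down = slip_down,
                      slip_up = slip_up),
                 class = "stutter_model")
  chk_len <- 1:60
  d <- slip_down("AC", chk_len); u <- slip_up("AC", chk_len)
  if (any(d < 0) || any(u < 0) || any(d + u > 1)) {
    stop("slip probabilities must satisfy 0 <= slip_down + slip_up <= 1")
  }
  if (d[1] != 0) stop("slip_down must be 0 at repeat length 1")
  m
}

#' A stutter-free model
#'
#' Convenience constructor: zero slippage at any number of cycles, so reads
#' reproduce the template allele exactly.
#' @export
zero_stutter_model <- function() {
  stutter_model(cycles = 0L,
                slip_down = function(unit, repeat_length) rep(0, length(repeat_length)),
                slip_up = function(unit, repeat_length) rep(0, length(repeat_length)))
}

#' @export
print.stutter_model <- function(x, ...) {
  cat("stutter_model:", x$cycles, "effective cycles\n")
  cat("  per-cycle slip (AC x13): down",
      signif(x$slip_down("AC", 13), 3), "up", signif(x$slip_up("AC", 13), 3), "\n")
  invisible(x)
}

#' Predict the stutter distribution of one allele
#'
#' Deterministic dynamic-programming realization: the read-length
#' distribution equals \code{cycles} applications of the single-cycle
#' transition kernel \{-1: slip_down, 0: 1 - slip_down - slip_up,
#' +1: slip_up\} to a point mass at the template allele, with an absorbing
#' floor at length 1.
#'
#' @param model a \code{stutter_model}.
#' @param allele template repeat length (integer >= 1).
#' @param unit repeat unit string (default "AC").
#' @return named numeric vector of probabilities over repeat lengths
#'   (names are lengths); sums to 1.
#' @export
predict_histogram <- function(model, allele, unit = "AC") {
  stopifnot(inherits(model, "stutter_model"))
  allele <- as.integer(allele)
  if (is.na(allele) || allele < 1L) stop("allele must be an integer >= 1")
  lens <- seq.int(1L, allele + model$cycles)
  p <- numeric(length(lens))
  p[allele] <- 1
  if (model$cycles > 0L) {
    d <- model$slip_down(unit, lens); d[1] <- 0
    u <- model$slip_up(unit, lens)
    s <- 1 - d - u
    n <- length(lens)
    for (cyc in seq_len(model$cycles)) {
      p <- p * s +
        c((p * d)[-1], 0) +          # from length l+1 slipping down
        c(0, (p * u)[-n])            # from length l-1 slipping up
    }
  }
  names(p) <- lens
  p
}

#' Predict the stutter distribution of a (possibly biallelic) genotype
#'
#' Convex combination \code{fractionA * predict(alleleA) + (1 - fractionA) *
#' predict(alleleB)}.
#'
#' @inheritParams predict_histogram
#' @param alleleA,alleleB template repeat lengths.
#' @param fractionA template fraction of allele A, in [0, 1] (default 0.5).
#' @return named numeric probability vector over repeat lengths.
#' @export
predict_mixture <- function(model, alleleA, alleleB, fractionA = 0.5,
                            unit = "AC") {
  if (fractionA < 0 || fractionA > 1) stop("fractionA must be in [0, 1]")
  pa <- predict_histogram(model, alleleA, unit)
  pb <- predict_histogram(model, alleleB, unit)
  lens <- seq.int(1L, max(length(pa), length(pb)))
  out <- numeric(length(lens)); names(out) <- lens
  out[names(pa)] <- fractionA * pa
  out[names(pb)] <- out[names(pb)] + (1 - fractionA) * pb
  out
}

# vectorized C-cycle slippage walk over a vector of current repeat lengths;
# shared by sample_histogram() and the batched dataset simulator, and kept
# independent of the DP in predict_histogram() so the two can cross-check
walk_lengths <- function(lens, unit, model) {
  if (model$cycles == 0L || length(lens) == 0L) return(lens)
  for (cyc in seq_len(model$cycles)) {
    d <- model$slip_down(unit, lens)
    d[lens <= 1L] <- 0
    u <- model$slip_up(unit, lens)
    r <- runif(length(lens))
    lens <- lens - (r < d) + (r >= d & r < d + u)
  }
  lens
}

#' Sample a stuttered read histogram
#'
#' Monte-Carlo counterpart of \code{\link{predict_histogram}}: each read
#' independently draws a template allele according to \code{fractionA}, then
#' performs a \code{cycles}-step slippage walk.  Empirical frequencies
#' converge to \code{\link{predict_mixture}} as \code{n_reads} grows.
#'
#' @inheritParams predict_mixture
#' @param alleles one or two template repeat lengths.
#' @param n_reads number of reads to draw (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return named integer vector: read counts by repeat length (empty for
#'   \code{n_reads = 0}).
#' @export
sample_histogram <- function(model, alleles, n_reads, fractionA = 0.5,
                             unit = "AC", seed = NULL) {
  stopifnot(inherits(model, "stutter_model"))
  if (n_reads < 0) stop("n_reads must be >= 0")
  set_seed_if(seed)
  if (n_reads == 0L) return(setNames(integer(0), character(0)))
  alleles <- as.integer(alleles)
  start <- if (length(alleles) == 1L) rep(alleles, n_reads) else
    ifelse(runif(n_reads) < fractionA, alleles[1], alleles[2])
  lens <- walk_lengths(start, unit, model)
  tab <- table(lens)
  setNames(as.integer(tab), names(tab))
}
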