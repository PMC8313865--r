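# Panel design: mutability filters, amplicon rules, precursor assembly and
# in-silico MlyI digestion.

make_loci <- function(units, counts) {
  data.frame(locus_id = sprintf("L%02d", seq_along(units)),
             unit = units, ref_repeat_count = counts,
             stringsAsFactors = FALSE)
}

test_that("hyper-mutable selection keeps AC/AG > 10 and A/G > 6 repeats, strictly", {
  panel <- make_loci(c("AC", "AC", "AG", "AG", "A", "A", "G", "ACG", "AT"),
                     c(12L, 10L, 11L, 9L, 7L, 6L, 8L, 15L, 20L))
  sel <- select_hypermutable_loci(panel)
  expect_setequal(sel$locus_id, c("L01", "L03", "L05", "L07"))
  # boundary is strict: exactly 10 di-repeats / 6 mono-repeats are dropped
  expect_false("L02" %in% sel$locus_id)
  expect_false("L06" %in% sel$locus_id)
  # filtering is idempotent
  expect_identical(select_hypermutable_loci(sel), sel)
})

test_that("reverse-complement unit classes are pooled only when requested", {
  panel <- make_loci(c("GT", "CT", "T", "C"), c(12L, 12L, 8L, 8L))
  pooled <- select_hypermutable_loci(panel, unify_revcomp = TRUE)
  expect_setequal(pooled$locus_id, c("L01", "L02", "L03", "L04"))
  strict <- select_hypermutable_loci(panel, unify_revcomp = FALSE)
  expect_equal(nrow(strict), 0L)
})

test_that("malformed units are rejected with the locus named", {
  panel <- make_loci(c("AC", "ACAC"), c(12L, 12L))
  expect_error(select_hypermutable_loci(panel), "L02")
  panel2 <- make_loci(c("AX"), 12L)
  expect_error(select_hypermutable_loci(panel2), "L01")
})

test_that("amplicon check enforces the TTAA exclusion and ~150bp size", {
  good <- strrep("ACGG", 37)          # 148 bp, no TTAA
  expect_true(check_amplicon(good)$pass)
  bad <- paste0(strrep("ACGG", 30), "TTAA", strrep("GC", 13))
  chk <- check_amplicon(bad)
  expect_false(chk$pass)
  expect_true("TTAA" %in% chk$reasons)
  short <- strrep("ACGG", 20)         # 80 bp
  chk2 <- check_amplicon(short)
  expect_false(chk2$pass)
  expect_true("length" %in% chk2$reasons)
  expect_true(check_amplicon(strrep("ACGG", 30), tol = 31)$pass)
  expect_error(check_amplicon("ACGU"), "non-ACGTN")
})

test_that("precursor assembly follows the printed element order and budget", {
  k <- mip_constants()
  # fixed elements: 23 + 23 + 54 + 2x3 = 106 nt, arm budget 44 nt
  expect_equal(nchar(k$mly1_f) + nchar(k$mly1_r) + nchar(k$backbone) + 6, 106)
  fw <- "ACGTACGTACGTACGTACGT"        # 20 nt
  rv <- "TGCATGCATGCATGCATGCA"        # 20 nt
  p <- assemble_precursor(fw, rv)
  expect_s3_class(p, "mip_precursor")
  expect_equal(nchar(p$full_sequence), 146)
  expect_identical(p$full_sequence,
                   paste0(k$mly1_f, fw, "NNN", k$backbone, "NNN",
                          revcomp(rv), revcomp(k$mly1_r)))
  # exactly the two adapter-internal MlyI recognition occurrences
  n_sites <- length(gregexpr("GAGTC", p$full_sequence, fixed = TRUE)[[1]]) +
    length(gregexpr("GACTC", p$full_sequence, fixed = TRUE)[[1]])
  expect_equal(n_sites, 2L)
})

test_that("assembly rejects MlyI-bearing arms and over-long precursors", {
  expect_error(assemble_precursor("ACGTGAGTCACGTACGTACG", "TGCATGCATGCATGCATGCA"),
               "MlyI")
  expect_error(assemble_precursor("ACGTGACTCACGTACGTACG", "TGCATGCATGCATGCATGCA"),
               "MlyI")
  long_arm <- strrep("ACGT", 7)  # 28 nt; 28 + 28 + 106 = 162 > 150
  expect_error(assemble_precursor(long_arm, long_arm), "longer")
})

test_that("MlyI digestion removes exactly the adapters, ~105 nt from 150", {
  fw <- "ACGGTACGGTACGGTACGGTAC"      # 22 nt
  rv <- "TGCCATGCCATGCCATGCCATG"      # 22 nt
  p <- assemble_precursor(fw, rv)     # 150 nt total
  expect_equal(nchar(p$full_sequence), 150)
  active <- digest_precursor(p)
  expect_lte(abs(nchar(active) - 105), 3)
  # arms and backbone survive intact; adapters are gone
  expect_identical(active, paste0(fw, "NNN", mip_constants()$backbone, "NNN",
                                  revcomp(rv)))
  expect_false(grepl(mip_constants()$mly1_f, active, fixed = TRUE))
  expect_error(digest_precursor("ACGTACGTACGT"), "adapter")
})

test_that("digest(assemble(x)) round-trips arms and backbone for random arms", {
  set.seed(42)
  for (i in 1:20) {
    repeat {
      fw <- paste(sample(c("A", "C", "G", "T"), sample(18:22, 1),
                         replace = TRUE), collapse = "")
      rv <- paste(sample(c("A", "C", "G", "T"), sample(18:22, 1),
                         replace = TRUE), collapse = "")
      ok <- tryCatch({assemble_precursor(fw, rv); TRUE},
                     error = function(e) FALSE)
      if (ok) break
    }
    p <- assemble_precursor(fw, rv)
    expect_identical(digest_precursor(p),
                     paste0(fw, "NNN", mip_constants()$backbone, "NNN",
                            revcomp(rv)))
  }
})

test_that("design_panel yields validated oligos and reports rejections", {
  set.seed(7)
  panel <- synthetic_panel(12, flank_length = 30, seed = 7)
  pool <- design_panel(panel, tol = 200)  # wide tol: amplicons are short here
  expect_true(all(nchar(pool$full_sequence) <= 150))
  for (s in pool$full_sequence) {
    expect_equal(length(gregexpr("GAGTC|GACTC", s)[[1]][
      gregexpr("GAGTC|GACTC", s)[[1]] > 0]), 2L)
  }
  # loci not in the output are accounted for as rejections
  expect_setequal(c(pool$locus_id, names(attr(pool, "rejected"))),
                  panel$locus_id)
})
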