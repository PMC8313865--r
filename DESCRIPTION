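Package: strlineage
Title: Retrospective Cell Lineage Reconstruction from Targeted Short Tandem Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for short tandem repeat (STR) based single-cell
    lineage reconstruction with duplex molecular inversion probe (MIP) panels:
    selection of hyper-mutable STR loci and assembly/in-silico digestion of MIP
    precursor oligos; a per-cycle slippage Markov-chain model of PCR stutter
    with deterministic histogram prediction and Monte-Carlo read simulation;
    clonal-expansion lineage simulation under the stepwise mutation model;
    read-to-histogram conversion against an enumerated STR-variant reference;
    correlation-based genotype calling with population-level biallelic
    separation; mutation-count distance matrices and neighbor-joining tree
    reconstruction with median-genotype rooting; loci-subsampling bootstrap
    with transfer bootstrap expectation (TBE) branch support; per-branch
    hypergeometric population-enrichment tests; and rooted-tree comparison by
    the normalized triples distance, including coverage-subsampling curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
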