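---
title: "STR-based single-cell lineage reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STR-based single-cell lineage reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strlineage)
```

## The problem

Somatic cells accumulate mutations at every division, so the genome of each
cell carries a record of its ancestry. Short tandem repeats (STRs) are the
most prolific source of such somatic variation: they gain and lose repeat
units through replication slippage at rates orders of magnitude above point
mutations, and their mutability is predictable from the repeat unit and
length. Targeting thousands of hyper-mutable STRs in single cells — here
with duplex molecular inversion probes (MIPs) — therefore supports
*retrospective* cell-lineage reconstruction: no recorder transgene is
needed, the mutations are already there.

The practical obstacles are (i) PCR stutter, which blurs each locus's read
histogram around the true repeat number; (ii) allelic ambiguity at
autosomal loci; and (iii) missing data from shallow or failed capture.
`strlineage` implements the complete computational pipeline — panel design,
stutter modelling, genotype calling, distance-based tree building, branch
support, clade enrichment, and tree comparison — together with a
first-class simulator that generates benchmarks with known ground truth.

## Panel design

Loci are selected by the mutability rule used for hyper-mutable panels:
AC- and AG-type dinucleotide repeats longer than 10 repeats, and A- and
G-type mononucleotide repeats longer than 6 repeats (strict inequalities;
`select_hypermutable_loci()`). Repeat units are reduced to their canonical
rotation, and reverse-complement classes are pooled by default (GT counts
as AC) — a flag disables the pooling because strand conventions differ
between annotation sources.

Candidate amplicons are rejected if they contain the TTAA motif
(incompatible with the downstream whole-genome-amplification chemistry) or
stray from ~150 bp. The tolerance around 150 bp is configurable
(default ±30 bp) since "approximately 150 bp" does not pin an exact band.

A precursor oligo is assembled in the fixed order

```
5'-[Mly1_F] [fw arm] [UMI] [backbone] [UMI] [revcomp(rv arm)] [revcomp(Mly1_R)]-3'
```

with the adapter and backbone constants available from `mip_constants()`.
The fixed elements total 106 nt, leaving a 44-nt budget for the two arms
under the 150-nt synthesis limit. Targeting arms are chosen by a
documented heuristic — length 18–25 nt, GC 30–70 %, no homopolymer run of
five, Wallace-rule melting proxy 2(A+T)+4(G+C) within 46–82 — rather than
a full thermodynamic primer scorer, which is out of scope. Any arm or
junction creating an extra MlyI recognition word (GAGTC/GACTC on either
strand) is rejected, because MlyI digestion must cut only at the two
adapter-internal sites. `digest_precursor()` simulates the blunt
GAGTC(N5) cut; the recognition sites sit so that digestion removes exactly
the two 23-nt adapters, turning a 150-nt precursor into a 104-nt active
MIP (the expected ~105 bp product).

## The stutter model

Amplification stutter is modelled as a per-cycle Markov chain on repeat
length: during each effective cycle a molecule of length $L$ loses one
unit with probability $d(u, L)$, gains one with probability $g(u, L)$, and
is copied faithfully otherwise, with length 1 an absorbing floor for
downward slippage. A sequenced read is an independent $C$-step walk from
the template allele. Two deliberate simplifications:

* **single-step slippage** — multi-unit jumps are represented as multiple
  cycles, the simplest chain consistent with stepwise slippage;
* **no PCR branching** — reads are i.i.d. walks, matching the calibration
  language of stutter being "equivalent to $C$ cycles"; MIP libraries
  behave like $C \approx$ 15–20, and the package default is the midpoint
  $C = 17$.

The default per-cycle probabilities rise logistically with repeat length
and are unit-class specific (mononucleotide repeats noisier than
dinucleotide):

$$d(u, L) = \frac{p_u}{1 + e^{-(L - L_u)/s_u}}, \qquad g(u, L) = 0.3\,d(u, L)$$

with $(p_u, L_u, s_u) = (0.04, 12, 3)$ for mononucleotides and
$(0.02, 18, 4)$ for longer units. At $C = 17$ this yields roughly 7 %
single-unit down-stutter for an (AC)×13 locus — the regime reported for
MIP capture. The published per-cycle constants of the underlying stutter
calibration are not reproduced here, so all parameters are plain R
functions the user can replace.

`predict_histogram()` is the deterministic counterpart: $C$ applications
of the single-cycle kernel to a point mass, a small dynamic program whose
mean drifts by $C\,(g - d)$ per the closed form when far from the floor.
`sample_histogram()` keeps an independent Monte-Carlo code path (the walk,
not the DP) so the two can cross-validate; the test suite checks total
variation < 0.01 at $10^5$ reads.

## Genotype calling

A histogram is genotyped by correlation matching: candidate mono-allelic
genotypes (observed support ± 2 repeat units — stutter rarely travels
further at ≤ 20 cycles) and all balanced 50/50 biallelic pairs of those
candidates are scored by the Pearson correlation between observed and
predicted distributions over a shared support window, padded by one guard
bin on each side so that point-mass cases stay well-defined. A call
requires at least 10 reads and correlation ≥ 0.95 (confidence
threshold 0.05), the thresholds used throughout. The mono-allelic optimum
is preferred unless the best biallelic pair beats it by more than 0.01
correlation; the balanced mixture fraction reflects that allelic imbalance
modelling is deferred.

Biallelic loci are then split population-wide: allele values pooled across
cells are partitioned at the largest gap, and if the two cluster centers
are separated by **more than three** repeat units the locus becomes two
mono-allelic pseudo-loci, each cell's alleles assigned to the nearer
center. Loci below that separation are kept as a single column holding the
lower allele and flagged low-heterogeneity — they still contribute signal,
at the documented cost of inflated terminal branches. (Whether a published
pipeline drops or keeps such loci is ambiguous; keeping them is the
default here and the separation threshold is exposed.)

## Distances, trees, rooting

The pairwise cell distance is the **mutation count**: the number of shared
genotyped pseudo-loci at which the repeat values differ, normalized by the
shared-locus count (the raw count is available behind a flag; the
normalization choice is not printed in the source material, and
missing-at-random data favor the normalized form). Pairs sharing fewer
than `min_shared = 50` loci are undefined — below that the distance is too
noisy to trust — and only an actually disconnected cell graph is an error.

Trees are built by neighbor joining (`ape::nj`) over this matrix with
lexicographic label ordering for deterministic tie-breaking and negative
branches clamped to zero. NJ stands in for the external FastTree2 used in
production settings: the distance matrix is the method-defining object,
the agglomerator is interchangeable, and `write_phylip()` exports the
matrix for any external tool.

Rooting uses the **median genotype** of a designated founder-like group
(lower median per pseudo-locus for even counts). Two modes:
`"outgroup"` appends the median genotype as a synthetic taxon, rebuilds,
roots on it and drops it; the default `"nearest_edge"` keeps the topology
and roots on the edge minimizing the attachment residual
$\overline{d(v,A)} + \overline{d(v,B)} - \overline{\delta_T(A,B)}$ over
the edge's split $A|B$, where $d(v,\cdot)$ are mutation-count distances
from the median genotype and $\delta_T$ the patristic distances. On clean
balanced simulations the two modes agree clade-for-clade (tested); they
can differ on star-like groups with long private branches, where root
placement is genuinely underdetermined.

## Branch support and enrichment

Support uses a **loci-subsampling bootstrap**: each replicate keeps two
thirds of the pseudo-locus columns (leaving out about a third of the loci
per round), rebuilds distance and tree, and branches are scored by the
**transfer bootstrap expectation**: for a branch $b$ with light-side size
$p$, $\mathrm{TBE}(b) = 1 - \overline{\delta(b, T_r)}/(p - 1)$, where
$\delta$ is the minimum bipartition Hamming distance over all branches of
the replicate (trivial branches included, which caps $\delta$ at $p-1$).
$B = 100$ replicates is the default (no published value to match), and
70 % is the conventional significance threshold. Felsenstein
presence/absence proportions are intentionally not the default — TBE
degrades gracefully when single cells jump around, which is exactly the
failure mode of noisy single-cell data.

Population structure on a rooted tree is assessed per internal branch with
an upper-tail hypergeometric test — $k$ label leaves among the $n$ subtree
leaves, drawn from $N$ labeled leaves of which $K$ carry the label —
with Benjamini–Hochberg adjustment across all (branch, label) pairs; raw
p-values are reported alongside since no correction convention is printed
for the figures this emulates.

## Tree comparison

Rooted reconstructions are scored by the **normalized triples distance**:
the fraction of the $\binom{n}{3}$ leaf triples whose induced rooted
topology differs. An unresolved (polytomous) triple counts as different
from any resolved one by default, matching the comparison-tool convention
this mirrors; `resolved_only = TRUE` restricts both numerator and
denominator to mutually resolved triples. Enumeration is exhaustive and
vectorized, practical to a few hundred leaves. `coverage_curve()` drives
the subsampling analysis: histograms are thinned to each target coverage,
re-genotyped, re-reconstructed and compared against the full-data tree.

## The simulator and what it does (not) show

`simulate_benchmark_tree()` emulates a nine-level clonal-expansion
experiment: lineages sampled every 12–15 divisions (uniform per level),
binary branching at levels 1–5 and single-lineage continuation afterwards,
giving exactly 32 leaves whose divergence times are spread across the
design. (A naive "4 daughters per level" design capped at 32 leaves would
exhaust the cap by level 3 and leave the deeper levels unbranched, so the
binary layout is the default; any per-level branching vector can be
passed.) Genotypes evolve under the symmetric stepwise mutation model at
$10^{-3}$ per locus per sampling generation — the scale estimated for
such benchmarks; the per-generation unit is the default
parameterization since that is the unit in which the estimate is made,
with a per-division flag. Reads are drawn through the stutter walk at
30× per-locus coverage, 5 000 mono-allelic AC loci.

The simulator reproduces stutter, stepwise mutation, and
missing-by-threshold data. It does **not** model WGA allelic dropout
beyond missing-at-random coverage, flank sequencing errors, indels inside
repeats, or CNVs. Passing the benchmark therefore demonstrates the
pipeline's correctness and its robustness to stutter-type noise — not
immunity to every artifact of real single-cell libraries.

## Benchmark and numerical choices

`run_benchmark()` composes the whole pipeline and scores it against the
simulation truth:

```{r benchmark, eval = FALSE}
bench <- run_benchmark(seed = 1)
bench
#> Simulated lineage benchmark (seed 1)
#>   9 sampling levels, 32 cells, 5000 loci, rate 0.001/generation, 17 stutter cycles, 30x coverage
#>   call rate            0.996
#>   genotype accuracy    0.9997
#>   mutation rate est.   1.02e-03 (true 1.00e-03)
#>   median TBE           100.0% over 29 true splits (100 replicates)
#>   triples distance     0.0000 (rooted reconstruction vs truth)
```

The TBE here is computed for the *true* sampling-level splits against the
bootstrap replicates, so it directly measures how reproducibly the data
support the known history. The mutation-rate estimator is the mean
per-generation genotype-change fraction along the known tree (leaf versus
founder, divided by depth in generations); reversal mutations bias it
down and miscalls bias it up, both at second order at these rates.

Problem sizes in the test suite are chosen for speed without changing the
study conditions: the full 5 000-locus benchmark runs once (~30 s), the
zero-noise end-to-end oracle uses a mutation rate of $4\times10^{-3}$ over
3 000 loci so that every true branch carries ≥ 20 expected mutations —
at $10^{-3}$ a branch has a ~0.7 % chance of carrying none, which would
make exact topology recovery unidentifiable regardless of pipeline
correctness. That choice is an identifiability requirement of the oracle,
fixed analytically, not a tuning knob.

Other numerical conventions collected in one place: ties in NJ are broken
by lexicographic cell id; candidate-scoring windows are padded by one
guard bin; biallelic cluster ties assign to the lower center; the
lower median is used for even-sized groups; permutation-valid
hypergeometric p-values are super-uniform rather than uniform because the
statistic is discrete.

## Known limitations

* The stutter parameterization is a calibrated default, not a fit to a
  specific instrument; real libraries should refit `slip_down`/`slip_up`.
* Balanced biallelic mixtures ignore WGA allelic imbalance.
* The largest-gap 1-D split is a deliberately simple haplotyper; it can
  mis-assign when population allele clouds overlap.
* NJ is consistent only for nearly additive matrices; very low coverage or
  tiny panels can produce distances outside that regime (the bootstrap and
  `min_shared` guard against over-interpretation).
* Triples enumeration is $O(n^3)$; beyond a few hundred cells a sampled
  approximation would be needed (not implemented).
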