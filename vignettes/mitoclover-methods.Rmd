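---
title: "Methods: comparative mitogenomics and tRNA-like structure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics and tRNA-like structure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoclover)
```

## Scope

`mitoclover` analyses annotated insect mitochondrial genomes — the circular
15–16 kb molecules carrying 13 protein-coding genes (PCGs), 22 tRNAs, two
rRNAs and one large non-coding control region. It computes the standard
comparative statistics of the field (composition and strand skews, codon
usage bias, pairwise Ka/Ks), catalogues the repeat architecture of control
regions, and — its central feature — detects *tRNA-like structures*:
control-region segments that fold into a cloverleaf and carry an anticodon
identical to one of the genome's own tRNAs. A deterministic synthetic
mitogenome generator provides ground truth so that every stage is testable
without any sequence download.

## Data model

A `mito_record` stores the deposited (majority / J strand) sequence and an
ordered feature table using 0-based half-open coordinates; a feature may
cross the origin of the circular molecule, represented by a `wrap` flag
rather than split spans. GenBank's 1-based closed coordinates are converted
only at the I/O boundary. Gene labels are normalized onto a fixed 37-token
vocabulary; the two leucine and serine tRNAs are disambiguated by anticodon
(trnL1 = CUN / TAG, trnL2 = UUR / TAA, trnS1 = AGN / GCT, trnS2 = UCN /
TGA), falling back to a product note, and erroring rather than guessing.
All coding-sequence work uses NCBI translation table 5 (invertebrate
mitochondrial): 62 sense codons, stops TAA/TAG only, serine an 8-fold
family (TCN + AGN), TGA = Trp, ATA = Met.

## Composition and skews

AT-skew is (A − T)/(A + T) and GC-skew is (G − C)/(G + C), computed from
counts on the J strand as deposited for whole genomes; per-gene sense
strands are used only when explicitly requested. Ambiguity codes are
excluded from every numerator and denominator, and a skew whose denominator
is zero is reported as `NA`, never silently as 0. Positional composition is
computed over complete codons in frame 0, with GC12 the mean of the
first- and second-position G+C percentages.

## Codon-usage bias

RSCU is a codon's count divided by the mean count of its synonymous family.
ENC follows Wright's estimator generalized to the family-size structure of
the genetic code *in use*: size classes are derived from the code at run
time, so under table 5 they are 2-, 4-, 6- and 8-fold (no singleton class)
and the selection-free maximum equals the 62 sense codons rather than the
textbook 61. Per family with at least 2 codons the homozygosity is
F = (n·Σp² − 1)/(n − 1); F is averaged per size class and a class with no
measurable family is interpolated from its adjacent available classes
(Wright's averaging rule — under table 5 this case does not arise for
ordinary data). The result is clamped to [2, 62]. CBI follows
Bennetzen–Hall with the preferred codon of each degenerate family taken as
the record's own modal codon (a fixed preferred set can be supplied for
sensitivity analysis). The ENC-plot null expectation is
ENC\* = 2 + GC3 + 29/(GC3² + (1 − GC3)²). Correlations are Pearson on
untransformed values with two-sided p-values.

Counting pools all 13 PCGs per record, reading each CDS in frame 0,
dropping a terminal stop and trailing partial codon, and excluding internal
stops and ambiguity-containing codons from the counts (they are tallied as
diagnostics).

## Ka/Ks

Pairwise rates use Nei–Gojobori (1986) counting with Jukes–Cantor
correction. Site fractions are computed per codon position over the
alternative nucleotides that do not create a stop codon, so S + N = 3 ×
codons compared holds exactly. Codons differing at several positions are
averaged over all minimal mutational pathways with equal weights; pathways
passing through a stop are discarded (if all do, all are kept). Proportions
at or above 3/4 leave the correction undefined; such pairs are excluded
from per-gene means and counted. When gene lengths differ across records,
a codon-aware alignment is built by amino-acid-level global alignment
(identity scoring +2/−1, linear gap −5) back-threaded to codons, with gap
columns dropped pairwise. Exact column parity with any particular external
aligner is not promised.

## Control-region repeats

The control region is taken from an explicit annotation when present,
otherwise as the gap from the end of rrnS to the start of trnI, wrapping
the origin if needed. The tandem-repeat scanner compares the sequence with
itself at every offset (period): each match position seeds a candidate run
extended to the end that maximizes matches − mismatches subject to an
identity floor (ties toward the shorter, then the cleaner run), candidates
below the copy-number floor are dropped, and survivors are selected
greedily by score into a non-overlapping set; across periods, overlapping
reports keep the highest copies × identity. This scoring was chosen so a
clean planted array is reported at its exact extent instead of being
diluted by chance matches in its flanks. Fractional copy numbers are
reported. Poly-T tracts and TA repeats are maximal runs (TA phase
canonicalized to the earliest start); G+C-rich intervals are the positions
whose every covering window exceeds the threshold. Spacer conservation
(e.g. the trnS2–nad1 spacer) uses a center-star progressive alignment and
merges columns at or above 90% conservation into blocks of at least 4
columns.

## Cloverleaf folding and tRNA-like detection

`fold_cloverleaf()` searches exhaustively over arm-boundary placements in
the canonical geometry: acceptor stem 7 bp, D stem 3–4 bp with a 3–12 nt
loop, anticodon stem 5 bp with a 7-nt loop whose central triplet is the
anticodon, variable loop 3–23 nt, T stem 4–5 bp with a 3–9 nt loop, short
spacers (1–3 nt after the acceptor, 0–2 nt before the anticodon arm) and a
0–4 nt 3' tail. Watson–Crick and G–U pairs count as paired. The placement
maximizing the number of paired bases wins, ties broken by fewer
mismatches, then the leftmost anticodon. Defaults allow at most 1 mismatch
per stem and require at least 14 paired bases. The enumeration is
implemented in C++; a brute-force R enumeration of all placements verifies
it in the test suite.

`scan_control_region()` applies the same enumeration across both strands of
a control region with window lengths 55–90 nt and keeps candidates whose
anticodon is identical to one of the genome's 22 conventional tRNAs — the
anticodon-identity criterion; no consensus standard exists for calling
tRNA-like sequences, and an optional relaxed mode (any folded candidate) is
provided but is not the default. Each hit is scored by global-alignment
percent identity (match +1, mismatch −1, gap −2; identity over all
alignment columns, a shorter-sequence denominator is available behind a
flag) against the same-anticodon reference, given a p-distance, and tiered
at 65% (inclusive on the percent rounded to one decimal, since the boundary
is otherwise ambiguous).

Two scanning defaults are stricter than the single-window folder, and
deliberately so. A+T-rich DNA pairs so readily that the lenient geometry
folds spurious cloverleafs roughly every hundred bases of random
85%-A+T sequence. The scanner therefore (i) requires the classical
semi-invariant bases of genuine tRNAs — U33 immediately 5' of the
anticodon, a purine at 37, and the T-loop's TTC (T54–Ψ55–C56) motif — the
invariant-base constraint used by early tRNA gene-search algorithms, and
(ii) defaults to `min_paired = 20`. This operating point was calibrated
once against a seeded null model (random 85% A+T, 1 kb): it leaves about
0.1 false calls per kb while planted unmutated copies are always
recovered. Both knobs are exposed; lowering them admits more heavily
mismatched structures at the cost of false positives, which matters for
real mitochondrial tRNAs whose T-loops can deviate from the TTC consensus.
Windows sharing an anticodon anchor are treated as one candidate: among
placements tied on pairing quality, the reference alignment decides the
reported extent. Overlapping hits are deduplicated greedily keeping the
highest match percent.

## Synthetic data

The generator emulates a darkling-beetle-like mitogenome: the typical
invertebrate gene order with the 23/14 J/N strand split; PCGs with ATN
starts, TAA stops and no internal stops, their codons sampled from
independent per-base probabilities under the configured composition; tRNAs
built from a cloverleaf template with perfectly complementary Watson–Crick
stems (so each folds with zero mismatches by construction), the designed
anticodon, and the U33/R37/TTC signature that real tRNAs carry; rRNAs and
the control region as seeded random sequence; and a control region between
rrnS and trnI closing the circle. Defaults reflect the conditions reported
across tenebrionid mitogenomes: genome A+T 71%, AT-skew 0.11, GC-skew
−0.26, control region 1000 bp (the observed range is roughly 930–1154 bp)
at 85% A+T, cohorts of 33 species. Genes on the minority strand are
sampled with mirrored skews so the configured J-strand asymmetry
materializes after reverse complementation. Gene overlaps (e.g. the
atp6/atp8 junction of real genomes) are not simulated; junctions get 0–3 bp
spacers, with an 18 bp spacer at trnS2–nad1.

Planting copies a conventional tRNA into the control region and mutates
non-anticodon positions i.i.d. at the requested rate, preserving the
anticodon so ground truth honors the identity criterion. Cohorts evolve on
a star phylogeny by substitutions only (no indels, keeping downstream
comparisons alignment-free); `synonymous_only` mode proposes only
third-position silent changes, which are closed within a synonymous family
under table 5, so no pairwise comparison between descendants can be read
as nonsynonymous by parsimony pathway counting — first-position silent
changes (Leu CTA ↔ TTA) would open mixed pathways. Mixed mode biases
proposals toward silent changes 3:1 to mimic purifying selection.

What passing tests on this generator do *not* show: real control regions
contain indels, heteroplasmy and structural variation the generator omits;
real tRNAs deviate from the template geometry (trnS1 typically lacks the
D arm); and real codon usage reflects selection the neutral sampler lacks.
Detection thresholds validated here should be re-examined before being
applied to distant taxa.

## Numerical and determinism choices

All randomness flows through R's RNG from a single integer seed; the same
seed yields byte-identical records. Re-running the pipeline on identical
inputs produces byte-identical outputs (no timestamps in data files;
single-threaded contract). Rounding for display is 3 decimals for skews
and 1–2 for percentages; raw doubles are kept internally. Undefined values
(skew with zero denominator, omega with ks = 0, Jukes–Cantor past 3/4) are
explicit `NA`s with flags, never silent zeros.

## Problem sizes in the shipped tests

The test suite and acceptance script generate their inputs at run time:
single 15–16 kb genomes, cohorts of 2–5 species for rate estimation,
1 kb control regions, 50 seeds × 4 mutation rates for the planted-recall
curve, and brute-force oracle comparisons on inputs up to 200 bp (tandem
repeats) and 75 nt (cloverleaf placements). These sizes were chosen so the
whole suite completes in about a minute while every oracle comparison
remains exhaustive.
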