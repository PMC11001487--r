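---
title: "Designing degenerate PCR primers from multiple sequence alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate PCR primers from multiple sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenpcr)
```

## The problem

PCR assays that must amplify a gene across many related organisms cannot rely
on a single reference sequence: any fixed primer will mismatch some of the
targets, biasing amplification toward the reference's nearest relatives.
`degenpcr` designs primer pairs directly from a nucleotide multiple sequence
alignment (MSA). Where the alignment is perfectly conserved it uses concrete
primers; where limited variation exists it can fall back to degenerate IUPAC
bases, so a single synthesized primer mix covers every observed variant. The
package also evaluates user-supplied primers against the same quality rules
(test mode) and looks primers up in the designed candidate lists (search
mode).

## Pipeline overview

1. **Input and alignment.** FASTA or Clustal input is validated against the
   IUPAC alphabet (`.` becomes `-`; `U` is rejected: the model is DNA-only).
   Equal-length gapped input is treated as aligned; an explicit flag
   overrides the inference, because equal-length *unaligned* collections
   exist. Unaligned multi-sequence input is delegated to an external MAFFT
   executable (`--globalpair` or `--localpair`, `--maxiterate 1000`); the
   adapter is injectable so pipelines can substitute their own aligner. No
   alignment algorithm is re-implemented here.
2. **Column profiles and consensus.** Each alignment column is summarized by
   A/C/G/T/gap counts (degenerate input codes contribute fractionally). A
   column becomes: a deletion mark when its gap fraction reaches
   `gap_threshold` (default 0.5); the single top base when that base's
   frequency reaches `majority_threshold` (default 0.9, ties broken
   A < C < G < T for determinism); otherwise the smallest IUPAC code covering
   every base at or above `minor_threshold` (default 0.1). The defaults
   minimize degeneracy while still covering recurrent variation; all three
   are settings.
3. **Conserved regions.** Maximal runs of single-base, non-gap consensus
   columns at least one primer long (18 by default) are the conserved
   regions, exportable as BED. A design is feasible only if the span from
   the first region's start to the last region's end can hold the minimum
   amplicon (100 bp default); infeasible templates return the consensus and
   a no-primer notice rather than an error.
4. **Candidates and filters.** Every window of 18-30 columns inside scope is
   a candidate in both orientations (a reverse candidate is the reverse
   complement of the window, keeping forward coordinates). Hard filters
   remove candidates; penalties only demote them.
5. **Pairing.** Surviving candidates are ranked by penalty and the forward x
   reverse cross-product is examined in combined-penalty order, one block
   (1600 pairs by default) at a time, accepting pairs that satisfy the
   amplicon, melting-temperature and annealing constraints and that reuse no
   primer, until five pairs are found.

## Quality rules

Hard filters (any failure disqualifies):

* **Degeneracy.** No degenerate code in either terminal trimer; no `N`
  anywhere; at most one 3-fold code (B/D/H/V) and two 2-fold codes
  (R/Y/S/W/K/M) per primer. The 3' end must bind exactly; a fully degenerate
  position multiplies the mix without improving coverage.
* **Deletions** (consensus windows only). No deletion mark in a terminal
  trimer, at most three consecutive and six total, and the deletions must
  not push the gap-free length under the minimum.
* **GC content and clamp.** Expected GC fraction (degenerate codes contribute
  the G/C share of their base set) within 40-60% inclusive, and at most
  three *consecutive* G/C bases at the 3' terminus. The consecutive-run
  reading of the clamp keeps a strong but not over-stabilized 3' end; a
  window-count variant was considered and rejected because it disqualifies
  primers whose 3' runs are short but whose near-terminal composition is
  merely average.
* **Tandem repeats.** Non-overlapping tandem duplication events (a k-mer
  immediately followed by itself): more than two duplicated dinucleotides,
  more than one duplicated trinucleotide, or any duplicated tetranucleotide
  disqualifies. Counting tandem events (rather than all repeated k-mer
  occurrences anywhere) matches how repeats promote slippage and misbinding;
  scattered recurrences of a dinucleotide are unavoidable in any 20-mer.
  k-mers longer than 4 are not examined.
* **Complementary ends.** A primer whose 3'-terminal trimer is the reverse
  complement of its 5'-terminal trimer can fold back or dimerize
  end-to-end and is disqualified. The rule deliberately compares the two
  termini only: an internal match far from the 3' end does not prime.
* **Size.** Gap-free length within 18-30 bp.
* **Temperature.** In test mode the melting-temperature window (50-65
  degrees C by default) is a hard check applied to every expansion of a
  degenerate primer (min and max must sit inside the window). In design
  mode an out-of-window mean melting temperature accrues penalty instead
  (1 penalty unit per degree), mirroring how ranking, not exclusion, is the
  appropriate response to a tunable property.

Penalty rules (never disqualify, only demote):

* **Hairpins.** One unit per window matching the triloop motif (5-bp track,
  complementary first/last base, G second, A second-to-last) or the
  analogous 6-bp tetraloop motif; degenerate primers take the worst case
  over expansions. The tetraloop geometry is a symmetric extension of the
  triloop and is isolated in one function should a different geometry be
  preferred.
* **3' dimerization.** One unit when the duplex free energy of the
  3'-terminal 5-mer falls strictly below -3 kcal/mol (e.g. `GGTGG`):
  a very stable 3' end seeds primer dimers.

All weights are settings; only relative ranking matters for output order.

## Thermodynamic model

Duplex enthalpy and entropy are sums over nearest-neighbor dinucleotide
stacks plus initiation terms for the terminal base pairs and a symmetry
correction for self-complementary oligos. The parameter table (unified DNA
nearest-neighbor set) ships as a versioned TSV
(`inst/extdata/nn_unified_v1.tsv`) so alternates can be swapped; free energy
is evaluated at 37 degrees C as `dH - T dS`, which keeps the table
internally consistent by construction.

Melting temperature uses the two-state formula

```
Tm(K) = 1000 dH / (dS + 16.6 log10[monovalent] + R ln(CT / b))
```

with `b = 4` for non-self-complementary duplexes (1 otherwise), `CT` the
total oligo concentration (50 nM default) and 50 mM monovalent ions. Two
placements of the classic `16.6 log10[Na+]` salt correction are defensible:
added to the converted Celsius temperature, or inside the entropy
denominator. We place it in the denominator: for primer-length oligos it is
then numerically equivalent to the published entropy salt correction
(`0.368 (N/2) ln[Na+]`, with `16.6/ln 10 = 7.21` against `0.368 x 19 = 6.99`
per natural-log unit for a 20-mer), and it keeps typical well-formed 18-30
bp primers inside the default 50-65 window, which the additive placement
does not (it depresses every primer by ~21.6 degrees and empties the
window). Degenerate primers are expanded (up to `expansion_cap`, default 64)
and the min/mean/max over the mix reported: hard filtering uses min/max
(every species must melt in-window), ranking and pairing use the mean
(stable under small mixes).

The amplicon's melting temperature uses the GC/length estimate
`81.5 + 0.41 GC% + 16.6 log10[monovalent] - 675/len`. The pair's annealing
temperature combines it with the less stable primer,
`Ta = 0.3 min(Tm_f, Tm_r) + 0.7 Tm_product - 14.9`, and each primer's mean
Tm must lie within 5 degrees of `Ta`. Comparing primers to the raw product
melting temperature instead is structurally unsatisfiable - a 100-500 bp
product melts 10-25 degrees above any admissible primer - so that reading
was rejected; a plain pairwise-difference rule is available via
`annealing_rule = "difference"`.

## Pair optimization

Pairs are examined in exact combined-penalty order (ties: forward rank, then
reverse rank), processed in blocks of `block_size` (1600) with early stop at
`max_pairs` (5). Because the enumeration order is the exact penalty order,
the result provably equals a brute-force scan of the full cross-product with
greedy uniqueness - the property the test suite asserts against an
independent oracle. To bound memory the candidate lists are truncated to the
best 2000 each before the cross-product (only relevant for templates
yielding more candidates than that; the truncation drops the worst-penalty
tail). Amplicon length is measured from the forward window's start to the
reverse window's end in forward coordinates (bp 0 at the 5' end), melting
temperatures of a pair may differ by at most 1 degree, and accepted pairs
never reuse a forward or reverse sequence, so the output lists are unique.

## The synthetic-alignment generator

`generate_fixture_msa()` emulates a set of homologous gene sequences with
perfectly conserved primer-hosting sites: identical columns inside the
planted blocks, independent substitutions (default rate 0.2 per sequence and
column) and deletions (0.02) outside them. Defaults - five sequences, 400
columns, two 40-column blocks 160 columns apart - give a template whose two
blocks can host a pair with a >= 200 bp amplicon. It is deterministic under
a seed. What it does *not* emulate: indel blocks shared across subsets of
sequences, covarying columns, compositional skew, or alignment errors - so
green tests on these fixtures demonstrate the pipeline's mechanics, not
robustness to messy real-world alignments. Tests and the acceptance script
use this generator at its default problem size (a 400-column, five-sequence
alignment designs in a few seconds; the property suites use 50-60-column
masks and candidate lists of tens to hundreds).

## Numerical choices and degenerate inputs

* GC-range and temperature-window comparisons are inclusive, with a 1e-9
  tolerance against floating-point edge effects.
* Ties in consensus calling break A < C < G < T; candidate ranking breaks
  penalty ties by start, then length - all orderings are deterministic.
* The dimerization threshold is a strict inequality (`< -3 kcal/mol`), so a
  boundary 5-mer is not penalized.
* A column where no base reaches the minor threshold still covers the top
  base, so consensus calling is total.
* Primers too degenerate to expand (`> expansion_cap`) fail the
  expansion-based checks with an explanatory detail rather than erroring.
* Empty files, invalid characters (with record and position), ragged
  Clustal blocks and missing aligners all produce actionable errors.

## Known limitations

* The melting-temperature model is a two-state nearest-neighbor estimate
  with a monovalent-only salt correction; divalent cations (Mg2+),
  dangling ends and full secondary-structure partition functions are out of
  scope.
* Cross-dimerization between the forward and reverse primer of a pair is
  not screened (only each primer's own 3' end), and there is no
  mispriming screen against genomic background.
* Degenerate candidates are scored by worst case over expansions, which is
  conservative for large mixes.
* The conserved-region approach requires exact conservation; a column with
  a single substitution in one sequence breaks a region even though a
  degenerate primer could span it - the filtration approach covers that
  case at the cost of weaker guarantees.
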