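# degenpcr

Degenerate PCR primer design from nucleotide multiple sequence alignments.

## What it does, and for whom

PCR assays that target a gene family across many organisms — phage capsid
genes, nitrogenase variants, ribosomal markers — cannot be designed against a
single reference sequence without biasing amplification toward that
reference's relatives. `degenpcr` is for molecular ecologists and assay
designers who have an alignment (or a single sequence) and need primer pairs
that bind every member: it summarizes the alignment into a minimal-degeneracy
IUPAC consensus, finds the conserved regions able to host primers and a large
enough amplicon, and selects optimized unique pairs; degenerate bases are
admitted only within an explicit budget so the synthesized mix stays small.

The core quantities, in the field's standard notation:

- **Consensus calling**: per column, the single top base when its frequency
  ≥ 0.9; otherwise the smallest IUPAC code covering every base with
  frequency ≥ 0.1; a deletion mark when the gap fraction ≥ 0.5.
- **Duplex thermodynamics**: nearest-neighbor sums
  ΔG° = Σᵢ nᵢ ΔG°ᵢ + ΔG°init(term G·C) + ΔG°init(term A·T) + ΔG°sym,
  evaluated from tabulated ΔH°/ΔS° at 37 °C, and the two-state melting
  temperature
  Tm = ΣΔH / (ΣΔS + 16.6 log₁₀[Na⁺] + R ln(C_T/b)) − 273.15,
  with C_T = 50 nM, [Na⁺] = 50 mM, b = 4 (1 for self-complementary oligos).
- **Product/annealing temperatures**:
  Tm(product) = 81.5 + 0.41·%GC + 16.6 log₁₀[K⁺] − 675/ℓ and
  Ta = 0.3·min(Tm_f, Tm_r) + 0.7·Tm(product) − 14.9.
- **Quality rules**: degeneracy budget (no N; ≤1 three-fold, ≤2 two-fold
  codes; concrete terminal trimers), deletion budget, 40–60 % GC with a ≤3
  consecutive-G/C 3′ clamp, tandem k-mer repeat limits (k = 2, 3, 4),
  complementary-ends check, 18–30 bp size, 50–65 °C melting window; hairpin
  motifs and dimer-prone 3′ ends accrue rank penalties.

## Worked example

```r
library(degenpcr)

coll <- generate_fixture_msa(seed = 42)   # 5 sequences, two conserved blocks
res  <- run_design(coll)
res
#> Primer design (conserved approach)
#> Template: 400 columns; 2 conserved region(s)
#> Candidates: 334 forward, 309 reverse
#> Optimized pairs:
#>  pair                  forward fwd_start                     reverse rev_start
#>     1   ACCCCCTGCACGCCCTAAAGTA        60 CGACGACTCACGTATTCACACGATTTA       259
#>     2 CCCCCTGCACGCCCTAAAGTACAA        61 CCGACGACTCACGTATTCACACGATTT       260
#>     3     CCCCTGCACGCCCTAAAGTA        62   CGACTCACGTATTCACACGATTTAT       258
#>     4   CCCCTGCACGCCCTAAAGTACA        62 GACGACTCACGTATTCACACGATTTAT       258
#>     5  CCCCTGCACGCCCTAAAGTACAA        62  CGACGACTCACGTATTCACACGATTT       260
#>  amplicon_len   tm_diff annealing_tm penalty
#>           226 0.5235185     57.26091       0
#>           226 0.1344966     58.09132       0
#>           221 0.8652397     55.62845       0
#>           223 0.1902104     56.79684       0
#>           224 0.4830788     57.21436       0
```

The five pairs sit inside the two planted conserved blocks (forward 5′
starts at columns 60–62, reverse windows ending near column 285), amplify
221–226 bp (≥ the 100 bp minimum), and match melting temperatures within
1 °C; zero penalty means no hairpin/dimer motifs and in-window Tm. Primer
sequences are unique across pairs.

Evaluating foreign primers (test mode):

```r
run_test_mode(c("GTGCAGCGAGTGCATCCCGG", "GGACTTCGAGAAGGTGATC"))
#>                primer  pass filters_failed tm_mean penalty
#>  GTGCAGCGAGTGCATCCCGG FALSE     GC content    60.3       1
#>   GGACTTCGAGAAGGTGATC FALSE           Temp    47.9       0
#> Passed: 0 / 2 (0%)
```

The first primer is 70 % GC (outside 40–60 %) and its G/C-rich 3′ 5-mer
(`CCCGG`, ΔG < −3 kcal/mol) accrues a dimer penalty; the second fails only
the melting window (47.9 °C under the default 50 °C floor).

A thin command-line front end ships in `inst/scripts/degenpcr` with verbs
`design`, `test`, `search` and `fixture`; `design` writes a sectioned
plain-text `.dgp` report (settings, consensus, conserved regions, ranked
primer tables, pair table) that `parse_report()` reads back.

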