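Package: degenpcr
Title: Degenerate PCR Primer Design from Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs degenerate PCR primer pairs from nucleotide multiple
    sequence alignments or single sequences. Builds a minimal-degeneracy
    IUPAC consensus, locates conserved regions large enough to host primers
    and amplicons, enumerates candidate oligonucleotides, applies explicit
    quality filters (degeneracy budget, deletions, GC content and clamp,
    tandem k-mer repeats, complementary ends, size, melting temperature),
    scores hairpin and 3'-dimerization risk from nearest-neighbor
    thermodynamics, and selects optimized unique primer pairs under
    amplicon-length, melting-temperature and annealing-temperature
    constraints. Also provides test and search modes for evaluating
    user-supplied primers, and a synthetic-alignment generator for
    reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
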