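# Nearest-neighbor thermodynamics ---------------------------------------------
#
# Duplex enthalpy and entropy are accumulated over adjacent dinucleotide
# "stacks", plus initiation terms that depend on the terminal base pairs and a
# symmetry correction for self-complementary oligos. Gibbs free energy is
# evaluated at a fixed reference temperature (37 C); melting temperature uses
# the two-state formula with an oligo-concentration term and a monovalent-salt
# correction.

.NN_REF_T <- 310.15   # K, reference temperature for delta-G
.GAS_R <- 1.9872      # cal/(mol K)

#' Nearest-neighbor duplex parameter table
#'
#' Reads the versioned parameter file shipped with the package (unified DNA
#' nearest-neighbor set: 16 dinucleotide stacks, initiation terms for G/C and
#' A/T terminal pairs, and a symmetry correction). An alternate table with the
#' same layout can be supplied via `path`.
#'
#' @param path Path to a tab-separated table with columns `term`, `dH`
#'   (kcal/mol) and `dS` (cal/(mol K)). Defaults to the bundled table.
#' @return An object of class `nn_table`: list with `dH` and `dS` named
#'   vectors over the 16 stacks, `init_gc`, `init_at`, `sym` (each
#'   `c(dH, dS)`), and `ref_temp` in Kelvin.
#' @export
nn_params <- function(path = system.file("extdata", "nn_unified_v1.tsv",
                                         package = "degenpcr")) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- raw[!raw$term %in% c("INIT_GC", "INIT_AT", "SYM"), ]
  if (nrow(stacks) != 16L || anyDuplicated(stacks$term))
    stop("parameter table must contain exactly the 16 dinucleotide stacks")
  pick <- function(term) {
    row <- raw[raw$term == term, ]
    if (nrow(row) != 1L) stop("parameter table missing term ", term)
    c(dH = row$dH, dS = row$dS)
  }
  out <- list(
    dH = stats::setNames(stacks$dH, stacks$term),
    dS = stats::setNames(stacks$dS, stacks$term),
    init_gc = pick("INIT_GC"),
    init_at = pick("INIT_AT"),
    sym = pick("SYM"),
    ref_temp = .NN_REF_T
  )
  class(out) <- "nn_table"
  out
}

# Memoized default table (read once per session).
.nn_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nn_params()
    cache
  }
})

# Is a concrete sequence self-complementary (equal to its reverse complement)?
.self_complementary <- function(chars) {
  n <- length(chars)
  if (n %% 2L == 1L) return(FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  identical(chars, unname(rev(comp[chars])))
}

# Total dH (kcal/mol) and dS (cal/(mol K)) of a concrete character vector,
# including initiation and (optionally) symmetry terms.
.nn_sums <- function(chars, table, symmetry = TRUE) {
  n <- length(chars)
  if (n < 2L) stop("nearest-neighbor sums need length >= 2", call. = FALSE)
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("degenerate or gap characters: expand the sequence first",
         call. = FALSE)
  stacks <- paste0(chars[-n], chars[-1L])
  dH <- sum(table$dH[stacks])
  dS <- sum(table$dS[stacks])
  for (end in chars[c(1L, n)]) {
    init <- if (end %in% c("G", "C")) table$init_gc else table$init_at
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfc <- .self_complementary(chars)
  if (symmetry && selfc) {
    dH <- dH + table$sym[["dH"]]
    dS <- dS + table$sym[["dS"]]
  }
  list(dH = dH, dS = dS, self_complementary = selfc)
}

#' Gibbs free energy of a concrete duplex
#'
#' Sum of dinucleotide stack free energies plus the applicable initiation
#' terms, plus the symmetry term when the sequence is self-complementary,
#' evaluated at the table's reference temperature (37 C) as
#' `dG = dH - T * dS`.
#'
#' @param x Concrete A/C/G/T string, length >= 2. Degenerate input is a
#'   contract error: expand first (see [expand_degenerate()]).
#' @param table Parameter table from [nn_params()].
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g("GGTGG")  # strongly negative: a dimer-prone 3' end
#' @export
delta_g <- function(x, table = .nn_default()) {
  chars <- .chars(normalize_sequence(x))
  s <- .nn_sums(chars, table)
  unname(s$dH - table$ref_temp * s$dS / 1000)
}

#' Thermodynamic and pipeline settings
#'
#' One settings object feeds every module: thermodynamic conditions, filter
#' thresholds, candidate window sizes and pairing constraints. Defaults follow
#' standard degenerate-primer design practice: a 50-65 C melting-temperature
#' window, 50 mM monovalent ions, 50 nM primer concentration, 18-30 bp
#' primers, a 100 bp minimum amplicon and up to five returned pairs.
#'
#' @param tm_min,tm_max Melting-temperature window in Celsius.
#' @param monovalent Monovalent cation concentration in mol/L (houses both
#'   Na+ and K+).
#' @param primer_conc Total oligo concentration CT in mol/L.
#' @param symmetry_divisor The divisor b in the CT/b concentration term for
#'   non-self-complementary duplexes (self-complementary oligos use b = 1).
#' @param gas_constant R in cal/(mol K).
#' @param expansion_cap Maximum degeneracy expanded for thermodynamic and
#'   pattern evaluation.
#' @param gc_min,gc_max Allowed expected GC fraction.
#' @param clamp_max_run 3' clamp rule: at most this many consecutive G/C
#'   bases at the 3' terminus.
#' @param min_len,max_len Primer length bounds in bp (gap-free).
#' @param max_deletions,max_consecutive_deletions Deletion-filter budgets for
#'   consensus windows containing deletion marks.
#' @param dimer_dg_threshold 3'-terminal 5-mer free energy (kcal/mol) below
#'   which the dimerization penalty applies (strict inequality).
#' @param hairpin_weight,dimer_weight,tm_weight Penalty weights: per hairpin
#'   window hit, per dimer-prone 3' end, and per degree Celsius outside the
#'   melting-temperature window (design mode).
#' @param min_amplicon Minimum amplicon length in bp (forward 5' start to
#'   reverse 5' start).
#' @param max_tm_diff Maximum melting-temperature difference between the
#'   primers of a pair, Celsius.
#' @param max_annealing_diff Maximum distance of each primer's Tm from the
#'   pair's annealing temperature, Celsius.
#' @param annealing_rule `"product"`: annealing temperature from the amplicon
#'   (0.3 Tm_min + 0.7 Tm_product - 14.9) and each primer must sit within
#'   `max_annealing_diff` of it; `"difference"`: plain pairwise primer Tm
#'   difference bound instead.
#' @param block_size Pairs examined per block in pair optimization.
#' @param max_pairs Number of optimized pairs to return.
#' @param majority_threshold,minor_threshold,gap_threshold Consensus-calling
#'   thresholds: single-base call when the top base reaches
#'   `majority_threshold`; a base joins the degenerate set when its frequency
#'   reaches `minor_threshold`; a column becomes a deletion mark when its gap
#'   fraction reaches `gap_threshold`.
#' @return An object of class `primer_settings`.
#' @export
primer_settings <- function(tm_min = 50, tm_max = 65,
                            monovalent = 0.05, primer_conc = 50e-9,
                            symmetry_divisor = 4, gas_constant = .GAS_R,
                            expansion_cap = 64,
                            gc_min = 0.40, gc_max = 0.60,
                            clamp_max_run = 3,
                            min_len = 18, max_len = 30,
                            max_deletions = 6, max_consecutive_deletions = 3,
                            dimer_dg_threshold = -3.0,
                            hairpin_weight = 1.0, dimer_weight = 1.0,
                            tm_weight = 1.0,
                            min_amplicon = 100, max_tm_diff = 1.0,
                            max_annealing_diff = 5.0,
                            annealing_rule = c("product", "difference"),
                            block_size = 1600, max_pairs = 5,
                            majority_threshold = 0.9, minor_threshold = 0.1,
                            gap_threshold = 0.5) {
  annealing_rule <- match.arg(annealing_rule)
  s <- as.list(environment())
  nums <- s[vapply(s, is.numeric, TRUE)]
  if (any(unlist(nums[c("monovalent", "primer_conc", "min_len", "max_len",
                        "min_amplicon", "block_size", "max_pairs")]) <= 0))
    stop("settings must be positive", call. = FALSE)
  if (s$min_len > s$max_len) stop("min_len > max_len", call. = FALSE)
  if (s$majority_threshold < s$minor_threshold)
    stop("majority_threshold must be >= minor_threshold", call. = FALSE)
  class(s) <- "primer_settings"
  s
}

#' Melting temperature of a (possibly degenerate) primer
#'
#' Two-state nearest-neighbor melting temperature. For each concrete
#' expansion,
#' `Tm(K) = 1000 * dH / (dS + 16.6 log10(monovalent) + R ln(CT / b))`,
#' converted to Celsius. The monovalent-salt term enters the entropy
#' denominator; `b` is `symmetry_divisor` (4) for non-self-complementary
#' oligos and 1 for self-complementary ones. Degenerate primers are expanded
#' (up to `expansion_cap`) and the minimum, mean and maximum over the mix are
#' reported; hard filtering uses min/max, ranking and pairing use the mean.
#'
#' @param x IUPAC nucleotide string (gaps ignored), gap-free length >= 2.
#' @param settings [primer_settings()].
#' @param table [nn_params()].
#' @return Named numeric vector `c(min, mean, max)` in Celsius.
#' @export
melting_temperature <- function(x, settings = primer_settings(),
                                table = .nn_default()) {
  exps <- .expansions(x, cap = settings$expansion_cap)
  tms <- vapply(exps, .tm_one, 0, settings = settings, table = table)
  c(min = min(tms), mean = mean(tms), max = max(tms))
}

.tm_one <- function(chars, settings, table) {
  s <- .nn_sums(chars, table)
  b <- if (s$self_complementary) 1 else settings$symmetry_divisor
  denom <- s$dS + 16.6 * log10(settings$monovalent) +
    settings$gas_constant * log(settings$primer_conc / b)
  if (denom >= 0) stop("non-physical entropy denominator", call. = FALSE)
  1000 * s$dH / denom - 273.15
}

#' Product (amplicon) melting temperature
#'
#' GC-and-length based melting temperature of the PCR product:
#' `81.5 + 0.41 * GC% + 16.6 log10([monovalent]) - 675 / length`.
#'
#' @param gc_percent GC content of the product in percent (0-100).
#' @param monovalent Monovalent cation concentration, mol/L.
#' @param product_len Product length in bp (>= 1).
#' @return Temperature in Celsius.
#' @examples
#' product_annealing_tm(50, 0.05, 500)  # about 79.1 C
#' @export
product_annealing_tm <- function(gc_percent, monovalent, product_len) {
  stopifnot(gc_percent >= 0, gc_percent <= 100, product_len >= 1)
  81.5 + 0.41 * gc_percent + 16.6 * log10(monovalent) - 675 / product_len
}

#' Annealing temperature of a primer pair
#'
#' Standard PCR annealing-temperature estimate combining the product melting
#' temperature with the less stable primer:
#' `Ta = 0.3 * min(Tm_f, Tm_r) + 0.7 * Tm_product - 14.9`.
#'
#' @param tm_forward,tm_reverse Primer melting temperatures, Celsius.
#' @param tm_product Product melting temperature from
#'   [product_annealing_tm()].
#' @return Annealing temperature in Celsius.
#' @export
pair_annealing_tm <- function(tm_forward, tm_reverse, tm_product) {
  0.3 * pmin(tm_forward, tm_reverse) + 0.7 * tm_product - 14.9
}
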