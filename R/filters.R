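# Primer quality filters and penalty scoring ----------------------------------
#
# Seven hard filters (degeneracy budget, deletions, GC content + 3' clamp,
# tandem k-mer repeats, complementary ends, size, melting-temperature window)
# and two penalty rules (tri/tetraloop hairpin motifs, 3'-terminal 5-mer
# dimerization free energy). Hard filters disqualify; penalties only demote a
# primer in the ranking. Every rule is a pure function of (primer, settings).

.filter_outcome <- function(pass, detail = "") {
  list(pass = isTRUE(pass), detail = detail)
}

# Expected G/C content of a single code: fraction of its base set that is G/C.
.gc_weight <- function(chars) {
  map <- .iupac_map()
  sets <- map[chars]
  vapply(strsplit(sets, "", fixed = TRUE),
         function(b) mean(b %in% c("G", "C")), 0)
}

#' Degeneracy filter
#'
#' Disqualifies a primer when a degenerate code sits in the first or last
#' three bases, when any `N` (4-fold) code is present, when more than one
#' 3-fold code is present, or when more than two 2-fold codes are present.
#' Gap marks are handled by the deletion filter and ignored here.
#'
#' @param primer IUPAC nucleotide string.
#' @param settings [primer_settings()] (unused; kept for a uniform surface).
#' @return List with `pass` and `detail`.
#' @export
filter_degeneracy <- function(primer, settings = primer_settings()) {
  chars <- .degap(.chars(normalize_sequence(primer)))
  n <- length(chars)
  if (n == 0L) return(.filter_outcome(FALSE, "empty primer"))
  folds <- iupac_fold(chars)
  terminal <- unique(c(seq_len(min(3L, n)), seq.int(max(1L, n - 2L), n)))
  reasons <- character()
  if (any(folds[terminal] > 1L))
    reasons <- c(reasons, "degenerate code within a terminal trimer")
  if (any(folds == 4L))
    reasons <- c(reasons, "contains N (4-fold degenerate)")
  if (sum(folds == 3L) > 1L)
    reasons <- c(reasons, "more than one 3-fold degenerate code")
  if (sum(folds == 2L) > 2L)
    reasons <- c(reasons, "more than two 2-fold degenerate codes")
  .filter_outcome(length(reasons) == 0L, paste(reasons, collapse = "; "))
}

#' Deletion filter
#'
#' Applies to consensus windows carrying deletion marks (`-`). Disqualifies
#' when (i) a deletion sits in the first or last three columns, (ii) more than
#' `max_consecutive_deletions` deletions run consecutively, (iii) more than
#' `max_deletions` deletions occur in total, or (iv) the gap-free length drops
#' below `min_len`.
#'
#' @inheritParams filter_degeneracy
#' @export
filter_deletions <- function(primer, settings = primer_settings()) {
  chars <- .chars(normalize_sequence(primer))
  n <- length(chars)
  if (n == 0L) return(.filter_outcome(FALSE, "empty primer"))
  gap <- chars == .IUPAC_GAP
  reasons <- character()
  terminal <- unique(c(seq_len(min(3L, n)), seq.int(max(1L, n - 2L), n)))
  if (any(gap[terminal]))
    reasons <- c(reasons, "deletion within a terminal trimer")
  runs <- rle(gap)
  if (any(runs$lengths[runs$values] > settings$max_consecutive_deletions))
    reasons <- c(reasons, sprintf("more than %d consecutive deletions",
                                  settings$max_consecutive_deletions))
  if (sum(gap) > settings$max_deletions)
    reasons <- c(reasons, sprintf("more than %d total deletions",
                                  settings$max_deletions))
  # rule iv fires only when deletions caused the shortfall; a gapless short
  # primer is the size filter's business
  if (any(gap) && sum(!gap) < settings$min_len)
    reasons <- c(reasons, sprintf("deletions drop gap-free length to %d, below minimum %d",
                                  sum(!gap), settings$min_len))
  .filter_outcome(length(reasons) == 0L, paste(reasons, collapse = "; "))
}

#' GC content and 3' clamp filter
#'
#' The expected GC fraction of the primer (degenerate codes contribute the
#' G/C share of their base set) must lie in `[gc_min, gc_max]` inclusive, and
#' the run of consecutive G/C bases at the 3' terminus must not exceed
#' `clamp_max_run` (codes whose whole base set is G/C - G, C and S - extend
#' the run).
#'
#' @inheritParams filter_degeneracy
#' @export
filter_gc <- function(primer, settings = primer_settings()) {
  chars <- .degap(.chars(normalize_sequence(primer)))
  n <- length(chars)
  if (n == 0L) return(.filter_outcome(FALSE, "empty primer"))
  w <- .gc_weight(chars)
  frac <- mean(w)
  reasons <- character()
  if (frac < settings$gc_min - 1e-9 || frac > settings$gc_max + 1e-9)
    reasons <- c(reasons, sprintf("GC %.1f%% outside [%.0f%%, %.0f%%]",
                                  100 * frac, 100 * settings$gc_min,
                                  100 * settings$gc_max))
  strong <- chars %in% c("G", "C", "S")
  run <- match(FALSE, rev(strong), nomatch = n + 1L) - 1L
  if (run > settings$clamp_max_run)
    reasons <- c(reasons, sprintf(
      "%d consecutive G/C at the 3' end (clamp limit %d)",
      run, settings$clamp_max_run))
  .filter_outcome(length(reasons) == 0L, paste(reasons, collapse = "; "))
}

# Tandem duplication counts for one concrete character vector: greedy
# left-to-right scan counting non-overlapping events where a K-mer is
# immediately followed by itself.
.tandem_counts <- function(chars, ks = 2:4) {
  n <- length(chars)
  vapply(ks, function(k) {
    hits <- 0L
    i <- 1L
    while (i + 2L * k - 1L <= n) {
      if (all(chars[i:(i + k - 1L)] == chars[(i + k):(i + 2L * k - 1L)])) {
        hits <- hits + 1L
        i <- i + 2L * k
      } else i <- i + 1L
    }
    hits
  }, 0L)
}

#' Tandem k-mer repetition filter
#'
#' Counts non-overlapping tandem duplication events (a k-mer immediately
#' followed by itself) for k = 2, 3, 4 and disqualifies a primer with more
#' than two tandem dinucleotides, more than one tandem trinucleotide, or any
#' tandem tetranucleotide. Degenerate primers are scored by the worst case
#' over their expansions. k-mers longer than four are not examined.
#'
#' @inheritParams filter_degeneracy
#' @export
filter_repeats <- function(primer, settings = primer_settings()) {
  counts <- tryCatch(
    {
      exps <- .expansions(primer, cap = settings$expansion_cap)
      m <- vapply(exps, .tandem_counts, integer(3))
      apply(m, 1L, max)
    },
    error = function(e) return(NULL)
  )
  if (is.null(counts))
    return(.filter_outcome(FALSE, "degeneracy exceeds expansion cap"))
  reasons <- character()
  if (counts[1L] > 2L)
    reasons <- c(reasons, sprintf("%d tandem dinucleotides (limit 2)", counts[1L]))
  if (counts[2L] > 1L)
    reasons <- c(reasons, sprintf("%d tandem trinucleotides (limit 1)", counts[2L]))
  if (counts[3L] > 0L)
    reasons <- c(reasons, sprintf("%d tandem tetranucleotides (limit 0)", counts[3L]))
  .filter_outcome(length(reasons) == 0L, paste(reasons, collapse = "; "))
}

#' Complementary-ends filter
#'
#' Disqualifies a primer whose two ends can anneal to each other: the reverse
#' complement of the 3'-terminal trimer equals the 5'-terminal trimer.
#' Degenerate trimers fail when any expansion of the 3' trimer matches any
#' expansion of the 5' trimer.
#'
#' @inheritParams filter_degeneracy
#' @export
filter_complementary_ends <- function(primer, settings = primer_settings()) {
  chars <- .degap(.chars(normalize_sequence(primer)))
  n <- length(chars)
  if (n < 6L) return(.filter_outcome(FALSE, "shorter than 6 bases"))
  head3 <- paste(chars[1:3], collapse = "")
  tail3 <- paste(chars[(n - 2L):n], collapse = "")
  rc_tail <- expand_degenerate(reverse_complement(tail3),
                               cap = settings$expansion_cap)
  heads <- expand_degenerate(head3, cap = settings$expansion_cap)
  hit <- any(rc_tail %in% heads)
  .filter_outcome(!hit,
                  if (hit) sprintf("3' trimer %s is complementary to the 5' trimer %s",
                                   tail3, head3) else "")
}

#' Size filter
#'
#' Gap-free length must lie within `[min_len, max_len]`.
#'
#' @inheritParams filter_degeneracy
#' @export
filter_size <- function(primer, settings = primer_settings()) {
  n <- length(.degap(.chars(normalize_sequence(primer))))
  ok <- n >= settings$min_len && n <= settings$max_len
  .filter_outcome(ok, if (!ok) sprintf("length %d outside [%d, %d]",
                                       n, settings$min_len, settings$max_len)
                  else "")
}

#' Melting-temperature window filter
#'
#' Hard form of the temperature rule used in test mode: every concrete
#' expansion of the primer must melt within `[tm_min, tm_max]` inclusive.
#' (Design mode treats out-of-window melting as a penalty instead; see
#' [tm_range_penalty()].)
#'
#' @inheritParams filter_degeneracy
#' @param table [nn_params()].
#' @export
filter_tm_range <- function(primer, settings = primer_settings(),
                            table = .nn_default()) {
  tm <- tryCatch(melting_temperature(primer, settings, table),
                 error = function(e) NULL)
  if (is.null(tm))
    return(.filter_outcome(FALSE, "melting temperature not evaluable"))
  ok <- tm[["min"]] >= settings$tm_min - 1e-9 &&
    tm[["max"]] <= settings$tm_max + 1e-9
  .filter_outcome(ok, if (!ok)
    sprintf("Tm %.1f-%.1f C outside [%.0f, %.0f]",
            tm[["min"]], tm[["max"]], settings$tm_min, settings$tm_max)
    else sprintf("Tm %.1f C", tm[["mean"]]))
}

# Hairpin motif scan of one concrete character vector: triloop = 5-bp track
# with complementary first/last base, G at the second position and A at the
# second-to-last; tetraloop = the analogous 6-bp track.
.hairpin_hits <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(chars)
  hits <- 0L
  if (n >= 5L) for (i in seq_len(n - 4L)) {
    w <- chars[i:(i + 4L)]
    if (w[5L] == comp[[w[1L]]] && w[2L] == "G" && w[4L] == "A")
      hits <- hits + 1L
  }
  if (n >= 6L) for (i in seq_len(n - 5L)) {
    w <- chars[i:(i + 5L)]
    if (w[6L] == comp[[w[1L]]] && w[2L] == "G" && w[5L] == "A")
      hits <- hits + 1L
  }
  hits
}

#' Hairpin penalty
#'
#' Adds `hairpin_weight` per window matching the triloop or tetraloop motif.
#' Hairpin-prone primers are never disqualified, only ranked lower. Degenerate
#' primers take the worst case over expansions.
#'
#' @inheritParams filter_tm_range
#' @return Non-negative penalty contribution.
#' @export
hairpin_penalty <- function(primer, settings = primer_settings()) {
  exps <- .expansions(primer, cap = settings$expansion_cap)
  settings$hairpin_weight * max(vapply(exps, .hairpin_hits, 0L))
}

#' 3'-end dimerization penalty
#'
#' Computes the duplex free energy of the 3'-terminal 5-mer (worst case over
#' expansions) and adds `dimer_weight` when it is below `dimer_dg_threshold`
#' (strictly less than -3 kcal/mol by default): a very stable 3' end promotes
#' primer-dimer formation.
#'
#' @inheritParams filter_tm_range
#' @return Non-negative penalty contribution.
#' @export
end_dimer_penalty <- function(primer, settings = primer_settings(),
                              table = .nn_default()) {
  chars <- .degap(.chars(normalize_sequence(primer)))
  n <- length(chars)
  if (n < 5L) return(0)
  tail5 <- paste(chars[(n - 4L):n], collapse = "")
  dgs <- vapply(expand_degenerate(tail5, cap = settings$expansion_cap),
                delta_g, 0, table = table)
  if (min(dgs) < settings$dimer_dg_threshold) settings$dimer_weight else 0
}

#' Melting-temperature range penalty (design mode)
#'
#' `tm_weight` per degree Celsius the mean melting temperature lies outside
#' `[tm_min, tm_max]`.
#'
#' @inheritParams filter_tm_range
#' @return Non-negative penalty contribution.
#' @export
tm_range_penalty <- function(primer, settings = primer_settings(),
                             table = .nn_default()) {
  tm <- melting_temperature(primer, settings, table)[["mean"]]
  settings$tm_weight * max(0, settings$tm_min - tm, tm - settings$tm_max)
}

#' Evaluate a primer against every filter (test mode)
#'
#' Runs all hard filters plus the melting-temperature window check, and
#' accumulates the hairpin/dimer penalty score. The outcome labels mirror the
#' report vocabulary: Degeneracy, Deletions, GC content, Repeats, Comp. ends,
#' Size, Temp.
#'
#' @param primer IUPAC nucleotide string.
#' @param settings [primer_settings()].
#' @param table [nn_params()].
#' @return An object of class `filter_report`: list with `primer`, `outcomes`
#'   (named list of `pass`/`detail`), `penalty`, `tm` (named min/mean/max or
#'   `NULL`) and `failed`.
#' @export
evaluate_primer <- function(primer, settings = primer_settings(),
                            table = .nn_default()) {
  primer <- normalize_sequence(primer, what = "primer")
  if (!nchar(gsub("-", "", primer, fixed = TRUE)))
    stop("primer is empty", call. = FALSE)
  outcomes <- list(
    "Degeneracy" = filter_degeneracy(primer, settings),
    "Deletions"  = filter_deletions(primer, settings),
    "GC content" = filter_gc(primer, settings),
    "Repeats"    = filter_repeats(primer, settings),
    "Comp. ends" = filter_complementary_ends(primer, settings),
    "Size"       = filter_size(primer, settings),
    "Temp"       = filter_tm_range(primer, settings, table)
  )
  penalty <- tryCatch(
    hairpin_penalty(primer, settings) +
      end_dimer_penalty(primer, settings, table),
    error = function(e) NA_real_
  )
  tm <- tryCatch(melting_temperature(primer, settings, table),
                 error = function(e) NULL)
  out <- list(
    primer = primer,
    outcomes = outcomes,
    penalty = penalty,
    tm = tm,
    failed = !all(vapply(outcomes, `[[`, TRUE, "pass"))
  )
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Primer:", x$primer, "\n")
  failed <- names(x$outcomes)[!vapply(x$outcomes, `[[`, TRUE, "pass")]
  cat("Result:", if (x$failed) "FAIL" else "PASS", "\n")
  if (length(failed)) cat("Filters failed:", paste(failed, collapse = ", "), "\n")
  if (!is.null(x$tm))
    cat(sprintf("Tm (min/mean/max): %.1f / %.1f / %.1f C\n",
                x$tm[["min"]], x$tm[["mean"]], x$tm[["max"]]))
  if (!is.na(x$penalty)) cat("Penalty:", format(x$penalty), "\n")
  for (nm in failed)
    if (nzchar(x$outcomes[[nm]]$detail))
      cat("  -", nm, ":", x$outcomes[[nm]]$detail, "\n")
  invisible(x)
}

#' Filter names that failed in a report
#' @param report A `filter_report`.
#' @return Character vector of failed filter labels.
#' @export
failed_filters <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  names(report$outcomes)[!vapply(report$outcomes, `[[`, TRUE, "pass")]
}
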