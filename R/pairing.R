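# Candidate enumeration, ranking and pair optimization -------------------------
#
# Candidate primers are every window of allowed length within scope (conserved
# regions, or the whole consensus / a user range in filtration mode), in both
# orientations. Reverse candidates are the reverse complement of the window
# and keep their forward-strand coordinates. Hard filters remove candidates;
# survivors carry melting-temperature statistics and a penalty (hairpin +
# 3'-dimer + out-of-window melting temperature). Pairing walks the candidate
# cross-product in combined-penalty order, one block at a time, accepting
# pairs that satisfy the amplicon/Tm/annealing constraints and reuse no
# primer, until five optimized pairs are found.

.empty_candidates <- function() {
  data.frame(sequence = character(), orientation = character(),
             start = integer(), length = integer(),
             gap_free_length = integer(), degeneracy = numeric(),
             tm_min = numeric(), tm_mean = numeric(), tm_max = numeric(),
             penalty = numeric(), stringsAsFactors = FALSE)
}

# Evaluate one window (character vector of consensus codes) in one
# orientation; returns a one-row data frame or NULL if a hard filter fails.
.window_candidate <- function(codes, start, orientation, settings, table) {
  window <- paste(codes, collapse = "")
  oligo <- if (orientation == "forward") window else reverse_complement(window)
  if (!filter_deletions(oligo, settings)$pass) return(NULL)
  if (!filter_size(oligo, settings)$pass) return(NULL)
  if (!filter_degeneracy(oligo, settings)$pass) return(NULL)
  if (!filter_gc(oligo, settings)$pass) return(NULL)
  if (!filter_repeats(oligo, settings)$pass) return(NULL)
  if (!filter_complementary_ends(oligo, settings)$pass) return(NULL)
  oligo_clean <- gsub("-", "", oligo, fixed = TRUE)
  tm <- tryCatch(melting_temperature(oligo_clean, settings, table),
                 error = function(e) NULL)
  if (is.null(tm)) return(NULL)
  pen <- hairpin_penalty(oligo_clean, settings) +
    end_dimer_penalty(oligo_clean, settings, table) +
    settings$tm_weight * max(0, settings$tm_min - tm[["mean"]],
                             tm[["mean"]] - settings$tm_max)
  data.frame(sequence = oligo_clean, orientation = orientation,
             start = start, length = length(codes),
             gap_free_length = nchar(oligo_clean),
             degeneracy = degeneracy(oligo_clean),
             tm_min = tm[["min"]], tm_mean = tm[["mean"]], tm_max = tm[["max"]],
             penalty = pen, stringsAsFactors = FALSE)
}

#' Enumerate candidate primers
#'
#' Generates every window of length `min_len` to `max_len` within scope, in
#' both orientations, applies the hard filters and scores the survivors.
#' In `"conserved"` mode the scope is the conserved regions; in
#' `"filtration"` mode it is the whole consensus or the user-supplied
#' 0-based half-open `range`. Windows count alignment columns; deletion marks
#' inside a window are handled by the deletion filter and excised from the
#' oligo.
#'
#' @param consensus A `consensus_sequence` (or plain IUPAC string).
#' @param regions Conserved-region data frame (required in conserved mode).
#' @param range Optional `c(begin, end)` 0-based half-open window of columns
#'   (filtration mode).
#' @param settings [primer_settings()].
#' @param mode `"conserved"` or `"filtration"`.
#' @param table [nn_params()].
#' @return List with `forward` and `reverse` candidate data frames (0-based
#'   `start` on the forward consensus).
#' @export
enumerate_candidates <- function(consensus, regions = NULL, range = NULL,
                                 settings = primer_settings(),
                                 mode = c("conserved", "filtration"),
                                 table = .nn_default()) {
  mode <- match.arg(mode)
  codes <- if (inherits(consensus, "consensus_sequence")) consensus$codes
           else .chars(normalize_sequence(consensus))
  n <- length(codes)
  scopes <- if (mode == "conserved") {
    if (is.null(regions) || nrow(regions) == 0L)
      stop("conserved mode requires non-empty regions", call. = FALSE)
    Map(c, regions$start, regions$end)
  } else {
    if (is.null(range)) range <- c(0L, n)
    if (range[1L] < 0L || range[2L] > n || range[1L] >= range[2L])
      stop("range must be a valid half-open interval within the template",
           call. = FALSE)
    list(range)
  }
  fwd <- list(); rev <- list()
  for (scope in scopes) {
    lo <- scope[[1L]]; hi <- scope[[2L]]
    for (len in seq.int(settings$min_len, settings$max_len)) {
      if (hi - lo < len) next
      for (s in seq.int(lo, hi - len)) {
        w <- codes[(s + 1L):(s + len)]
        f <- .window_candidate(w, s, "forward", settings, table)
        if (!is.null(f)) fwd[[length(fwd) + 1L]] <- f
        r <- .window_candidate(w, s, "reverse", settings, table)
        if (!is.null(r)) rev[[length(rev) + 1L]] <- r
      }
    }
  }
  bind <- function(lst) {
    if (!length(lst)) return(.empty_candidates())
    df <- do.call(rbind, lst)
    unique(df)
  }
  list(forward = bind(fwd), reverse = bind(rev))
}

#' Rank candidates by accrued penalty
#'
#' Stable sort by penalty ascending, then start, then length; adds a 1-based
#' `rank` column.
#'
#' @param candidates Candidate data frame from [enumerate_candidates()].
#' @return The sorted data frame with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer()
    return(candidates)
  }
  out <- candidates[order(candidates$penalty, candidates$start,
                          candidates$length), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Expected GC percent and gap-free length of a consensus slice
# (0-based half-open columns).
.amplicon_stats <- function(codes, from, to) {
  slice <- .degap(codes[(from + 1L):to])
  list(gc_percent = 100 * mean(.gc_weight(slice)), len = length(slice))
}

#' Check the pairing constraints for one forward/reverse combination
#'
#' A pair is acceptable when the amplicon (forward 5' start to reverse 5'
#' start, i.e. the reverse window's end in forward coordinates) reaches
#' `min_amplicon`, the windows do not overlap, the mean melting temperatures
#' differ by at most `max_tm_diff`, and the annealing rule holds: with the
#' default `"product"` rule, each primer's mean Tm must lie within
#' `max_annealing_diff` of the pair's annealing temperature
#' ([pair_annealing_tm()] over the amplicon's GC and length); with the
#' `"difference"` rule, the primer Tm difference must stay below
#' `max_annealing_diff`.
#'
#' @param forward,reverse Single-row candidate data frames (or lists with
#'   fields `start`, `length`, `tm_mean`).
#' @param settings [primer_settings()].
#' @param consensus A `consensus_sequence` or IUPAC string supplying amplicon
#'   composition for the annealing rule.
#' @return List with `ok`, `amplicon_len`, `tm_diff`, `annealing_tm`,
#'   `product_tm` and `reasons`.
#' @export
pair_constraints <- function(forward, reverse, settings = primer_settings(),
                             consensus = NULL) {
  codes <- if (inherits(consensus, "consensus_sequence")) consensus$codes
           else if (is.character(consensus)) .chars(normalize_sequence(consensus))
           else NULL
  f_start <- forward$start; f_len <- forward$length
  r_start <- reverse$start; r_len <- reverse$length
  amplicon <- (r_start + r_len) - f_start
  reasons <- character()
  if (f_start + f_len > r_start)
    reasons <- c(reasons, "windows overlap or reverse lies 5' of forward")
  if (amplicon < settings$min_amplicon)
    reasons <- c(reasons, sprintf("amplicon %d bp < minimum %d bp",
                                  amplicon, settings$min_amplicon))
  tm_diff <- abs(forward$tm_mean - reverse$tm_mean)
  if (tm_diff > settings$max_tm_diff + 1e-9)
    reasons <- c(reasons, sprintf("Tm difference %.2f C > %.1f C",
                                  tm_diff, settings$max_tm_diff))
  product_tm <- NA_real_; annealing <- NA_real_
  if (settings$annealing_rule == "product") {
    if (is.null(codes))
      stop("the product annealing rule needs the consensus", call. = FALSE)
    stats <- .amplicon_stats(codes, f_start, r_start + r_len)
    product_tm <- product_annealing_tm(stats$gc_percent, settings$monovalent,
                                       stats$len)
    annealing <- pair_annealing_tm(forward$tm_mean, reverse$tm_mean, product_tm)
    off <- max(abs(forward$tm_mean - annealing),
               abs(reverse$tm_mean - annealing))
    if (off > settings$max_annealing_diff + 1e-9)
      reasons <- c(reasons, sprintf(
        "primer Tm %.1f C away from annealing temperature %.1f C",
        off, annealing))
  } else {
    if (tm_diff >= settings$max_annealing_diff)
      reasons <- c(reasons, sprintf("primer Tm difference %.2f C >= %.1f C",
                                    tm_diff, settings$max_annealing_diff))
  }
  list(ok = length(reasons) == 0L, amplicon_len = amplicon, tm_diff = tm_diff,
       annealing_tm = annealing, product_tm = product_tm, reasons = reasons)
}

.empty_pairs <- function() {
  data.frame(pair = integer(), forward = character(), fwd_start = integer(),
             fwd_length = integer(), reverse = character(),
             rev_start = integer(), rev_length = integer(),
             amplicon_len = integer(), tm_diff = numeric(),
             annealing_tm = numeric(), penalty = numeric(),
             stringsAsFactors = FALSE)
}

#' Select optimized primer pairs
#'
#' Walks the forward x reverse cross-product in combined-penalty order
#' (ties broken by forward then reverse rank), examining `block_size` pairs
#' per block, and accepts pairs that satisfy [pair_constraints()] and reuse
#' no already-accepted primer sequence, stopping at `max_pairs` pairs or
#' exhaustion. With zero acceptable pairs an empty table is returned and the
#' caller reports the no-primer notice.
#'
#' @param forward,reverse Ranked candidate data frames ([rank_candidates()]).
#' @param settings [primer_settings()].
#' @param consensus Consensus (see [pair_constraints()]).
#' @return Pair data frame; attribute `blocks_examined` counts processed
#'   blocks.
#' @export
pair_primers <- function(forward, reverse, settings = primer_settings(),
                         consensus = NULL) {
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    out <- .empty_pairs()
    attr(out, "blocks_examined") <- 0L
    return(out)
  }
  # keep the cross-product tractable; lists are penalty-sorted so the
  # truncation drops only the worst-ranked candidates
  cap <- 2000L
  if (nrow(forward) > cap) forward <- forward[seq_len(cap), , drop = FALSE]
  if (nrow(reverse) > cap) reverse <- reverse[seq_len(cap), , drop = FALSE]
  nf <- nrow(forward); nr <- nrow(reverse)
  combined <- outer(forward$penalty, reverse$penalty, `+`)
  fi <- as.vector(row(combined)); ri <- as.vector(col(combined))
  ord <- order(as.vector(combined), fi, ri)
  fi <- fi[ord]; ri <- ri[ord]
  accepted <- list()
  used_f <- character(); used_r <- character()
  blocks <- 0L
  total <- length(fi)
  for (block_start in seq.int(1L, total, by = settings$block_size)) {
    blocks <- blocks + 1L
    block <- seq.int(block_start, min(block_start + settings$block_size - 1L,
                                      total))
    for (k in block) {
      f <- forward[fi[k], ]; r <- reverse[ri[k], ]
      if (f$sequence %in% used_f || r$sequence %in% used_r) next
      chk <- pair_constraints(f, r, settings, consensus)
      if (!chk$ok) next
      accepted[[length(accepted) + 1L]] <- data.frame(
        pair = length(accepted) + 1L,
        forward = f$sequence, fwd_start = f$start, fwd_length = f$length,
        reverse = r$sequence, rev_start = r$start, rev_length = r$length,
        amplicon_len = chk$amplicon_len, tm_diff = chk$tm_diff,
        annealing_tm = chk$annealing_tm, penalty = f$penalty + r$penalty,
        stringsAsFactors = FALSE)
      used_f <- c(used_f, f$sequence); used_r <- c(used_r, r$sequence)
      if (length(accepted) >= settings$max_pairs) break
    }
    if (length(accepted) >= settings$max_pairs) break
  }
  out <- if (length(accepted)) do.call(rbind, accepted) else .empty_pairs()
  rownames(out) <- NULL
  attr(out, "blocks_examined") <- blocks
  out
}

#' Search for a primer in the candidate lists
#'
#' Exact, case-insensitive match of the query against the requested
#' orientation's ranked candidate list. On a miss the query is pipelined into
#' test mode and the filter report is returned; no alignment against the
#' template is attempted, so a missing primer may simply lie outside the
#' candidate scope.
#'
#' @param query Primer string (IUPAC alphabet).
#' @param candidates List with ranked `forward` and `reverse` data frames.
#' @param orientation `"forward"` or `"reverse"`.
#' @param settings [primer_settings()].
#' @return List with `found`; when found, `rank` (1-based); otherwise
#'   `report`, a `filter_report`.
#' @export
search_primer <- function(query, candidates,
                          orientation = c("forward", "reverse"),
                          settings = primer_settings()) {
  orientation <- match.arg(orientation)
  query <- normalize_sequence(query, what = "query primer")
  df <- candidates[[orientation]]
  hit <- which(df$sequence == query)
  if (length(hit))
    return(list(found = TRUE, rank = df$rank[hit[[1L]]]))
  list(found = FALSE, report = evaluate_primer(query, settings))
}
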