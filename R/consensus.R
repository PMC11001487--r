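# Consensus construction and conserved-region detection ------------------------
#
# An aligned collection is restructured into per-column base-count profiles.
# Each column is then assigned the minimal-degeneracy IUPAC code that covers
# every base reaching the minor-allele threshold, a single base when the top
# base reaches the majority threshold, or a deletion mark when gaps dominate.
# Conserved regions are the maximal runs of single-base, non-gap columns long
# enough to host a primer.

#' Per-column base-count profiles of an aligned collection
#'
#' One profile per alignment column, counting A, C, G, T and gap occurrences.
#' Degenerate input codes contribute fractionally to each base of their set
#' (an N adds 0.25 to each of the four bases), so column counts always sum to
#' the number of sequences.
#'
#' @param coll A [seq_collection()]; must be aligned.
#' @return An object of class `column_profiles`: list with `counts` (5 x n
#'   numeric matrix, rows A, C, G, T, `-`) and `depth` (sequence count).
#' @export
build_profiles <- function(coll) {
  stopifnot(inherits(coll, "seq_collection"))
  if (!is_aligned(coll))
    stop("build_profiles() requires an aligned collection", call. = FALSE)
  set <- Biostrings::DNAStringSet(unname(sequences(coll)))
  cm <- Biostrings::consensusMatrix(set)
  n <- nchar(sequences(coll)[[1L]])
  counts <- matrix(0, nrow = 5L, ncol = n,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  map <- .iupac_map()
  for (code in rownames(cm)) {
    if (!any(cm[code, ] > 0)) next
    if (code %in% c("A", "C", "G", "T", "-")) {
      counts[code, ] <- counts[code, ] + cm[code, ]
    } else if (code %in% names(map)) {
      bases <- iupac_base_set(code)
      for (b in bases)
        counts[b, ] <- counts[b, ] + cm[code, ] / length(bases)
    } else if (code %in% c("+", ".")) {
      counts["-", ] <- counts["-", ] + cm[code, ]
    }
  }
  out <- list(counts = counts, depth = length(sequences(coll)))
  class(out) <- "column_profiles"
  out
}

#' Reverse-strand view of column profiles
#'
#' Columns in reverse order with complemented base counts; the view of the
#' same alignment read 5' to 3' on the opposite strand.
#'
#' @param profiles A `column_profiles` object.
#' @return A `column_profiles` object.
#' @export
reverse_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "column_profiles"))
  counts <- profiles$counts[c("T", "G", "C", "A", "-"),
                            rev(seq_len(ncol(profiles$counts))), drop = FALSE]
  rownames(counts) <- c("A", "C", "G", "T", "-")
  out <- list(counts = counts, depth = profiles$depth)
  class(out) <- "column_profiles"
  out
}

#' Summarize profiles as a data frame
#'
#' @param x A `column_profiles` object.
#' @param ... Unused.
#' @return Data frame with 0-based `index`, per-base counts, `top_base` (ties
#'   broken A < C < G < T) and `top_ratio` (top count over depth).
#' @export
as.data.frame.column_profiles <- function(x, ...) {
  counts <- x$counts
  bases <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  top <- apply(bases, 2L, which.max)
  data.frame(
    index = seq_len(ncol(counts)) - 1L,
    A = counts["A", ], C = counts["C", ], G = counts["G", ],
    T = counts["T", ], gap = counts["-", ],
    top_base = rownames(bases)[top],
    top_ratio = bases[cbind(top, seq_along(top))] / x$depth,
    row.names = NULL
  )
}

#' Assign a minimal-degeneracy consensus code to every column
#'
#' A column becomes a deletion mark when its gap fraction reaches
#' `gap_threshold`. Otherwise, when the most common base accounts for at
#' least `majority_threshold` of the sequences the single base is called;
#' otherwise the smallest IUPAC code covering every base whose frequency
#' reaches `minor_threshold` (always including the top base) is called. Ties
#' for the top base break in the fixed order A < C < G < T.
#'
#' @param profiles A `column_profiles` object from [build_profiles()].
#' @param majority_threshold Frequency at or above which a single base is
#'   called (default 0.9).
#' @param minor_threshold Frequency at or above which a base joins the
#'   degenerate set (default 0.1).
#' @param gap_threshold Gap frequency at or above which the column becomes a
#'   deletion mark (default 0.5).
#' @return An object of class `consensus_sequence`: list with `codes`
#'   (character vector of IUPAC codes and `-` marks), `profiles`, and the
#'   thresholds used.
#' @export
assign_consensus <- function(profiles,
                             majority_threshold = 0.9,
                             minor_threshold = 0.1,
                             gap_threshold = 0.5) {
  stopifnot(inherits(profiles, "column_profiles"))
  stopifnot(majority_threshold > 0, majority_threshold <= 1,
            minor_threshold > 0, minor_threshold <= 1,
            majority_threshold >= minor_threshold)
  counts <- profiles$counts
  depth <- profiles$depth
  codes <- character(ncol(counts))
  for (i in seq_len(ncol(counts))) {
    col <- counts[, i]
    if (col[["-"]] / depth >= gap_threshold) {
      codes[i] <- .IUPAC_GAP
      next
    }
    base_ratio <- col[c("A", "C", "G", "T")] / depth
    top <- which.max(base_ratio)   # first max: tie-break A < C < G < T
    if (base_ratio[top] >= majority_threshold) {
      codes[i] <- names(base_ratio)[top]
    } else {
      cover <- names(base_ratio)[base_ratio >= minor_threshold]
      cover <- union(cover, names(base_ratio)[top])
      codes[i] <- iupac_code_for(cover)
    }
  }
  out <- list(codes = codes, profiles = profiles,
              majority_threshold = majority_threshold,
              minor_threshold = minor_threshold,
              gap_threshold = gap_threshold)
  class(out) <- "consensus_sequence"
  out
}

#' @export
print.consensus_sequence <- function(x, ...) {
  s <- consensus_string(x)
  cat("Consensus of", x$profiles$depth, "sequences,", length(x$codes),
      "columns; degeneracy", format(degeneracy(s)), "\n")
  for (i in seq(1L, nchar(s), by = 60L))
    cat(substr(s, i, min(i + 59L, nchar(s))), "\n")
  invisible(x)
}

#' Consensus as a single string
#' @param consensus A `consensus_sequence`.
#' @return IUPAC string including deletion marks.
#' @export
consensus_string <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_sequence"))
  paste(consensus$codes, collapse = "")
}

#' Find conserved regions in a consensus
#'
#' Maximal runs of single-base (fold 1), non-gap consensus columns with length
#' at least `min_len`; the regions able to host a primer without any
#' degenerate position. Coordinates are 0-based half-open on the forward
#' consensus.
#'
#' @param consensus A `consensus_sequence` (or plain IUPAC string).
#' @param min_len Minimum region length; defaults to the minimum primer
#'   length, 18.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `length`; zero rows when no region qualifies.
#' @export
find_conserved_regions <- function(consensus, min_len = 18) {
  stopifnot(min_len >= 1)
  codes <- if (inherits(consensus, "consensus_sequence")) consensus$codes
           else .chars(normalize_sequence(consensus))
  conserved <- codes %in% c("A", "C", "G", "T")
  runs <- rle(conserved)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values & runs$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             length = runs$lengths[keep])
}

#' Can the conserved regions host an amplicon?
#'
#' Checks whether some forward-primer window and reverse-primer window
#' (possibly in the same region) can span at least `min_amplicon` from the
#' forward primer's 5' start to the reverse primer's 5' start. Since regions
#' are already long enough to host a primer, this reduces to the largest span
#' from the first region's start to the last region's end.
#'
#' @param regions Data frame from [find_conserved_regions()].
#' @param min_amplicon Minimum amplicon length in bp; must be at least twice
#'   the minimum primer length.
#' @param template_len Consensus length, for bounds checking.
#' @param min_len Minimum primer length (default 18).
#' @return List with `feasible` (logical), `max_span` (bp) and `detail`.
#' @export
check_amplicon_feasibility <- function(regions, min_amplicon, template_len,
                                       min_len = 18) {
  if (min_amplicon < 2 * min_len)
    stop("min_amplicon must be at least twice the minimum primer length",
         call. = FALSE)
  if (nrow(regions) == 0L)
    return(list(feasible = FALSE, max_span = 0L,
                detail = "no conserved region can host a primer"))
  if (max(regions$end) > template_len)
    stop("regions extend beyond the template", call. = FALSE)
  max_span <- max(regions$end) - min(regions$start)
  feasible <- max_span >= min_amplicon
  list(feasible = feasible, max_span = max_span,
       detail = if (feasible) "" else
         sprintf("largest conserved span %d bp < minimum amplicon %d bp",
                 max_span, min_amplicon))
}
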