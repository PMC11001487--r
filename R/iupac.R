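#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide algebra ----------------------------------------------------
#
# The degenerate alphabet is the 15 IUPAC nucleotide codes plus the gap mark
# '-'. Each code denotes a non-empty subset of {A,C,G,T}; its "fold" is the
# subset size. Degeneracy of a sequence is the product of per-position folds
# over non-gap positions: the number of concrete oligo species in a
# synthesized degenerate primer mix.

.IUPAC_GAP <- "-"

#' IUPAC code table used throughout the package
#'
#' Named character vector mapping each IUPAC nucleotide code to the string of
#' concrete bases it denotes, taken from [Biostrings::IUPAC_CODE_MAP].
#' @keywords internal
.iupac_map <- function() Biostrings::IUPAC_CODE_MAP

#' Normalize and validate a nucleotide string
#'
#' Input is case-insensitive; `.` is normalized to the gap mark `-`.
#' `U` (uracil) is rejected: the package models DNA oligonucleotides only.
#'
#' @param x A single character string over the IUPAC alphabet.
#' @param what Label used in error messages (e.g. a record identifier).
#' @return The normalized uppercase string.
#' @examples
#' normalize_sequence("acgt.")  # "ACGT-"
#' @export
normalize_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- chartr(".", .IUPAC_GAP, toupper(x))
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad_u <- which(chars == "U")
  if (length(bad_u))
    stop(what, ": 'U' (uracil) at position ", bad_u[1L],
         "; only DNA input is supported", call. = FALSE)
  ok <- chars %in% c(names(.iupac_map()), .IUPAC_GAP)
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop(what, ": invalid character '", chars[pos], "' at position ", pos,
         call. = FALSE)
  }
  x
}

#' Per-code degeneracy fold
#'
#' @param codes Character vector of single IUPAC codes (may include `-`).
#' @return Integer vector: the number of concrete bases each code denotes
#'   (1 for A/C/G/T, 4 for N); `NA` for the gap mark.
#' @export
iupac_fold <- function(codes) {
  map <- .iupac_map()
  out <- nchar(map[codes])
  out[codes == .IUPAC_GAP] <- NA_integer_
  unname(as.integer(out))
}

#' Concrete base set denoted by an IUPAC code
#'
#' @param code A single IUPAC code.
#' @return Character vector of concrete bases (subset of A,C,G,T).
#' @export
iupac_base_set <- function(code) {
  if (code == .IUPAC_GAP) return(character())
  strsplit(.iupac_map()[[code]], "", fixed = TRUE)[[1L]]
}

#' Smallest IUPAC code covering a base set
#'
#' IUPAC codes biject with the non-empty subsets of {A,C,G,T}, so the smallest
#' covering code is the code whose base set equals the requested set.
#'
#' @param bases Character vector, a non-empty subset of A,C,G,T.
#' @return A single IUPAC code.
#' @export
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  stopifnot(length(bases) >= 1L, all(bases %in% c("A", "C", "G", "T")))
  key <- paste(bases, collapse = "")
  map <- .iupac_map()
  sets <- vapply(map, function(s)
    paste(sort(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "")
  names(map)[match(key, sets)]
}

#' Degeneracy of a degenerate sequence
#'
#' The product of per-position folds over non-gap positions; the number of
#' concrete oligo species in the corresponding primer mix.
#'
#' @param x IUPAC nucleotide string (gaps allowed, ignored).
#' @return A numeric scalar (can exceed integer range for long N-rich input).
#' @export
degeneracy <- function(x) {
  x <- normalize_sequence(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  chars <- chars[chars != .IUPAC_GAP]
  if (!length(chars)) return(1)
  prod(iupac_fold(chars))
}

#' Reverse complement of a degenerate sequence
#'
#' Degenerate codes are complemented elementwise on their base sets
#' (e.g. `R` = A/G maps to `Y` = C/T); gap marks are preserved in place.
#'
#' @param x IUPAC nucleotide string.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("WGC")  # "GCW"
#' @export
reverse_complement <- function(x) {
  x <- normalize_sequence(x)
  if (!nchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Complement of single IUPAC codes
#' @param codes Character vector of single codes.
#' @return Complemented codes, elementwise.
#' @keywords internal
complement_codes <- function(codes) {
  if (!length(codes)) return(character())
  strsplit(as.character(
    Biostrings::complement(Biostrings::DNAString(paste(codes, collapse = "")))
  ), "", fixed = TRUE)[[1L]]
}

#' Expand a degenerate sequence into its concrete species
#'
#' Enumerates the cartesian product of per-position base sets. Gap marks are
#' dropped, so every expansion is a gap-free A/C/G/T string.
#'
#' @param x IUPAC nucleotide string.
#' @param cap Maximum degeneracy that will be expanded (default 64); larger
#'   input is refused with the measured degeneracy in the error message.
#' @return Character vector of distinct concrete sequences; its length equals
#'   the degeneracy of `x`.
#' @examples
#' expand_degenerate("AR")  # "AA" "AG"
#' @export
expand_degenerate <- function(x, cap = 64) {
  x <- normalize_sequence(x)
  d <- degeneracy(x)
  if (d > cap)
    stop("degeneracy ", d, " exceeds expansion cap ", cap, call. = FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  chars <- chars[chars != .IUPAC_GAP]
  if (!length(chars)) return("")
  sets <- lapply(chars, iupac_base_set)
  grid <- do.call(expand.grid,
                  c(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

# Internal: character-vector views used by the filter engine ------------------

# Split a normalized sequence into its character vector.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Drop gap marks from a character vector.
.degap <- function(chars) chars[chars != .IUPAC_GAP]

# Expansions as a list of character vectors (gap-free).
.expansions <- function(x, cap = 64) {
  lapply(expand_degenerate(x, cap = cap), .chars)
}
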