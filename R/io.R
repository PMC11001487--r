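# Input/output: FASTA and Clustal reading, alignment delegation, reports ------

#' Sequence collection
#'
#' Ordered named nucleotide sequences with an alignment flag. Construct with
#' [read_fasta()], [read_clustal()], [generate_fixture_msa()] or directly.
#'
#' @param seqs Named character vector of IUPAC nucleotide strings.
#' @param aligned Logical; `NA` (default) infers: equal lengths and at least
#'   one gap character.
#' @return An object of class `seq_collection`.
#' @export
seq_collection <- function(seqs, aligned = NA) {
  if (!length(seqs)) stop("empty collection", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  seqs <- vapply(names(seqs), function(id)
    normalize_sequence(seqs[[id]], what = paste0("record '", id, "'")), "")
  if (is.na(aligned)) {
    lens <- nchar(seqs)
    aligned <- length(unique(lens)) == 1L &&
      (length(seqs) > 1L && any(grepl("-", seqs, fixed = TRUE)))
  }
  if (aligned && length(unique(nchar(seqs))) != 1L)
    stop("aligned collections must have equal-length sequences", call. = FALSE)
  structure(list(seqs = seqs, aligned = aligned), class = "seq_collection")
}

#' Sequences of a collection
#' @param coll A `seq_collection`.
#' @return Named character vector.
#' @export
sequences <- function(coll) {
  stopifnot(inherits(coll, "seq_collection"))
  coll$seqs
}

#' Is a collection aligned?
#' @param coll A `seq_collection`.
#' @return Logical.
#' @export
is_aligned <- function(coll) {
  stopifnot(inherits(coll, "seq_collection"))
  isTRUE(coll$aligned)
}

#' @export
print.seq_collection <- function(x, ...) {
  cat("Sequence collection:", length(x$seqs), "record(s),",
      if (is_aligned(x)) "aligned" else "unaligned", "\n")
  lens <- nchar(x$seqs)
  cat("Lengths:", if (length(unique(lens)) == 1L) lens[[1L]]
      else paste(range(lens), collapse = "-"), "\n")
  invisible(x)
}

#' Read a (multi-)FASTA file
#'
#' Records are validated against the IUPAC alphabet; `.` is normalized to `-`
#' and case is folded to upper. The alignment flag is inferred (equal lengths
#' and at least one gap) unless `aligned` is given, which is authoritative:
#' equal-length unaligned collections exist.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical or `NA` (infer).
#' @return A [seq_collection()].
#' @export
read_fasta <- function(path, aligned = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty file: no FASTA records in ", path, call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seq_collection(seqs, aligned = aligned)
}

#' Write a collection as FASTA
#'
#' @param coll A [seq_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(coll, path) {
  set <- Biostrings::BStringSet(sequences(coll))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Clustal-format alignment
#'
#' The file must begin with a CLUSTAL header line; interleaved blocks are
#' concatenated per identifier and conservation lines are ignored. Trailing
#' per-line residue counts are tolerated. Unknown tokens on the header line
#' are surfaced as a warning.
#'
#' @param path Path to a Clustal/CLUSTALW `.aln` file.
#' @return An aligned [seq_collection()].
#' @export
read_clustal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", toupper(lines[[1L]])))
    stop("not a Clustal file (missing CLUSTAL header): ", path, call. = FALSE)
  header_tokens <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  known <- grepl("^CLUSTAL", toupper(header_tokens)) |
    grepl("^[0-9.()]+$", header_tokens) |
    toupper(header_tokens) %in% c("W", "O", "X", "OMEGA", "MULTIPLE",
                                  "SEQUENCE", "ALIGNMENT", "FORMAT", "MSAPROBS",
                                  "MUSCLE", "MAFFT", "VERSION")
  if (any(!known))
    warning("unknown Clustal header token(s): ",
            paste(header_tokens[!known], collapse = " "), call. = FALSE)
  body <- lines[-1L]
  seqs <- list()
  order_ids <- character()
  block_ids <- character()
  block_width <- NA_integer_
  block_no <- 0L
  for (ln in body) {
    if (!nzchar(trimws(ln))) {
      if (length(block_ids)) { block_no <- block_no + 1L }
      block_ids <- character(); block_width <- NA_integer_
      next
    }
    # conservation lines hold only consensus symbols / whitespace
    if (grepl("^\\s", ln) || !grepl("[A-Za-z]", sub("^\\S+", "", ln))) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.~-]+)(\\s+\\d+)?\\s*$", ln))[[1L]]
    if (length(m) < 3L)
      stop("unparseable Clustal line in block ", block_no + 1L, ": ", ln,
           call. = FALSE)
    id <- m[[2L]]; chunk <- m[[3L]]
    if (is.na(block_width)) block_width <- nchar(chunk)
    if (nchar(chunk) != block_width)
      stop("inconsistent sequence-line lengths in Clustal block ",
           block_no + 1L, call. = FALSE)
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], chunk)
    block_ids <- c(block_ids, id)
  }
  if (!length(seqs)) stop("no sequences in Clustal file: ", path, call. = FALSE)
  out <- unlist(seqs[order_ids])
  if (length(unique(nchar(out))) != 1L)
    stop("Clustal records have unequal total lengths; truncated block?",
         call. = FALSE)
  seq_collection(out, aligned = TRUE)
}

#' Align a collection if needed
#'
#' Already-aligned input (or a single sequence) passes through unchanged.
#' Unaligned multi-sequence input is delegated to an external MAFFT
#' executable: `--globalpair` or `--localpair` with `--maxiterate 1000`.
#' The adapter is injectable so tests and callers can substitute any function
#' `(coll, mode) -> seq_collection`.
#'
#' @param coll A [seq_collection()].
#' @param mode `"global"` or `"local"` pairwise mode.
#' @param aligner Optional function `(coll, mode)` returning an aligned
#'   collection; defaults to the MAFFT adapter.
#' @param mafft Path to the MAFFT executable.
#' @return An aligned [seq_collection()].
#' @export
align_if_needed <- function(coll, mode = c("global", "local"),
                            aligner = NULL, mafft = "mafft") {
  mode <- match.arg(mode)
  stopifnot(inherits(coll, "seq_collection"))
  if (is_aligned(coll) || length(sequences(coll)) == 1L) return(coll)
  if (is.null(aligner)) aligner <- function(coll, mode) {
    if (!nzchar(Sys.which(mafft)))
      stop("no aligner available: '", mafft, "' not found on PATH; ",
           "supply a pre-aligned file (or use aligned = TRUE)", call. = FALSE)
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_fasta(coll, fin)
    flag <- if (mode == "global") "--globalpair" else "--localpair"
    status <- system2(mafft, c(flag, "--maxiterate", "1000", "--quiet", fin),
                      stdout = fout, stderr = FALSE)
    if (!identical(status, 0L) || file.size(fout) == 0L)
      stop("external aligner failed (exit status ", status, ")", call. = FALSE)
    read_fasta(fout, aligned = TRUE)
  }
  out <- aligner(coll, mode)
  if (!is_aligned(out)) stop("aligner returned unaligned output", call. = FALSE)
  out
}

# Report ----------------------------------------------------------------------

.DGP_VERSION <- "degenpcr-report v1"

.fmt_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character())
  df <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.4f", col) else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  c(paste(names(df), collapse = "\t"),
    apply(df, 1L, paste, collapse = "\t"))
}

#' Write a design report
#'
#' Sectioned plain-text report: a versioned header, the settings, the
#' consensus sequence, the conserved-region table, the ranked forward and
#' reverse primer tables (sequence, 0-based index, length, melting
#' temperature, penalty) and the pair table (amplicon length, annealing
#' temperature). A run with zero pairs carries an explicit no-primer notice.
#'
#' @param path Output path.
#' @param candidates List with `forward` and `reverse` ranked candidate data
#'   frames (may be `NULL`).
#' @param pairs Pair data frame from [pair_primers()] (may be `NULL`).
#' @param consensus A `consensus_sequence` (or `NULL`).
#' @param regions Conserved-region data frame (or `NULL`).
#' @param settings [primer_settings()].
#' @param notice Optional notice line (e.g. the no-primer message).
#' @return `path`, invisibly.
#' @export
write_report <- function(path, candidates = NULL, pairs = NULL,
                         consensus = NULL, regions = NULL,
                         settings = primer_settings(), notice = NULL) {
  out <- c(paste0("# ", .DGP_VERSION))
  out <- c(out, "", "[settings]")
  keep <- vapply(settings, function(v) is.numeric(v) || is.character(v), TRUE)
  out <- c(out, paste0(names(settings)[keep], "\t",
                       vapply(settings[keep], function(v) paste(v, collapse = ","), "")))
  if (!is.null(consensus)) {
    out <- c(out, "", "[consensus]", consensus_string(consensus))
  }
  if (!is.null(regions)) {
    out <- c(out, "", "[conserved_regions]", .fmt_table(regions))
    if (nrow(regions) == 0L) out <- c(out, "(none)")
  }
  for (side in c("forward", "reverse")) {
    df <- candidates[[side]]
    out <- c(out, "", paste0("[", side, "_primers]"))
    if (is.null(df) || nrow(df) == 0L) {
      out <- c(out, "(none)")
    } else {
      cols <- c("rank", "sequence", "start", "length", "tm_min", "tm_mean",
                "tm_max", "penalty")
      out <- c(out, .fmt_table(df[, intersect(cols, names(df)), drop = FALSE]))
    }
  }
  out <- c(out, "", "[pairs]")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- c(out, "(none)", "no primer found")
  } else {
    out <- c(out, .fmt_table(pairs))
  }
  if (!is.null(notice)) out <- c(out, "", "[notes]", notice)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Parse a design report
#'
#' Re-reads the sectioned report written by [write_report()]; the round-trip
#' recovers the primer and pair tables.
#'
#' @param path Path to a `.dgp` report.
#' @return List with `version`, `consensus` (string or `NULL`), `regions`,
#'   `forward`, `reverse`, `pairs` (data frames or `NULL`) and `notice`.
#' @export
parse_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[[1L]], "# "))
    stop("not a degenpcr report: ", path, call. = FALSE)
  version <- sub("^# ", "", lines[[1L]])
  section <- NA_character_
  bodies <- list()
  for (ln in lines[-1L]) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      bodies[[section]] <- character()
    } else if (!is.na(section) && nzchar(ln)) {
      bodies[[section]] <- c(bodies[[section]], ln)
    }
  }
  parse_tab <- function(body) {
    body <- body[body != "(none)" & body != "no primer found"]
    if (!length(body)) return(NULL)
    utils::read.delim(text = paste(body, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  list(
    version = version,
    consensus = if (length(bodies$consensus)) bodies$consensus[[1L]] else NULL,
    regions = parse_tab(bodies$conserved_regions),
    forward = parse_tab(bodies$forward_primers),
    reverse = parse_tab(bodies$reverse_primers),
    pairs = parse_tab(bodies$pairs),
    notice = c(if (any(bodies$pairs == "no primer found")) "no primer found",
               bodies$notes)
  )
}

#' Export conserved regions as BED
#'
#' Regions are written as 0-based half-open intervals on a single reference
#' named `seqname` (the consensus coordinate system).
#'
#' @param regions Data frame from [find_conserved_regions()].
#' @param path Output `.bed` path.
#' @param seqname Reference name used in the BED records.
#' @return `path`, invisibly.
#' @export
export_regions_bed <- function(regions, path, seqname = "consensus") {
  gr <- regions_as_granges(regions, seqname = seqname)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Conserved regions as a GRanges
#'
#' @inheritParams export_regions_bed
#' @return A [GenomicRanges::GRanges] (1-based closed internally; exports as
#'   0-based half-open BED).
#' @export
regions_as_granges <- function(regions, seqname = "consensus") {
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = paste0("conserved_", seq_len(nrow(regions)))
  )
}
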