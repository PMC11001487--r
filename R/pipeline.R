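# Pipeline orchestration: design, test and search runs -------------------------

.NO_PRIMER_NOTICE <- "no primer found"

#' Design primer pairs from a file or collection
#'
#' End-to-end run: read (FASTA or Clustal, sniffed from content), align if
#' needed, build column profiles, assign the minimal-degeneracy consensus,
#' and design primers. With the conserved approach (default for alignments)
#' candidates are drawn from conserved regions after an amplicon-feasibility
#' check; infeasible templates return the consensus and a no-primer notice
#' rather than an error. The filtration approach (default for a single
#' sequence, or on request) windows the whole consensus or a user range and
#' relies on the hard filters alone.
#'
#' @param input Path to a FASTA/Clustal file, or a [seq_collection()].
#' @param aligned Logical or `NA`; authoritative alignment flag for FASTA
#'   input.
#' @param align_mode `"global"` or `"local"` (passed to the external aligner).
#' @param approach `"auto"`, `"conserved"` or `"filtration"`.
#' @param range Optional 0-based half-open column range (filtration).
#' @param out Optional report path; when given, the sectioned report is
#'   written there.
#' @param settings [primer_settings()].
#' @param aligner Optional aligner injection (see [align_if_needed()]).
#' @return An object of class `design_result`: list with `collection`,
#'   `consensus`, `regions`, `feasibility`, `candidates` (ranked forward and
#'   reverse), `pairs`, `approach` and `notice` (`NULL` on success).
#' @export
run_design <- function(input, aligned = NA, align_mode = "global",
                       approach = c("auto", "conserved", "filtration"),
                       range = NULL, out = NULL,
                       settings = primer_settings(), aligner = NULL) {
  approach <- match.arg(approach)
  coll <- if (inherits(input, "seq_collection")) input
          else .read_any(input, aligned = aligned)
  coll <- align_if_needed(coll, mode = align_mode, aligner = aligner)
  single <- length(sequences(coll)) == 1L
  if (single && !is_aligned(coll)) coll$aligned <- TRUE
  profiles <- build_profiles(coll)
  consensus <- assign_consensus(profiles,
                                majority_threshold = settings$majority_threshold,
                                minor_threshold = settings$minor_threshold,
                                gap_threshold = settings$gap_threshold)
  if (approach == "auto") approach <- if (single) "filtration" else "conserved"
  regions <- find_conserved_regions(consensus, min_len = settings$min_len)
  feas <- NULL
  notice <- NULL
  candidates <- list(forward = .empty_candidates(), reverse = .empty_candidates())
  pairs <- .empty_pairs()
  proceed <- TRUE
  if (approach == "conserved") {
    feas <- check_amplicon_feasibility(regions, settings$min_amplicon,
                                       length(consensus$codes),
                                       min_len = settings$min_len)
    if (!feas$feasible) {
      notice <- paste0(.NO_PRIMER_NOTICE, ": ", feas$detail)
      proceed <- FALSE
    }
  }
  if (proceed) {
    candidates <- enumerate_candidates(
      consensus,
      regions = if (approach == "conserved") regions else NULL,
      range = range, settings = settings, mode = approach)
    candidates$forward <- rank_candidates(candidates$forward)
    candidates$reverse <- rank_candidates(candidates$reverse)
    if (nrow(candidates$forward) == 0L || nrow(candidates$reverse) == 0L) {
      notice <- paste0(.NO_PRIMER_NOTICE,
                       ": no candidate survived the hard filters")
    } else {
      pairs <- pair_primers(candidates$forward, candidates$reverse,
                            settings, consensus)
      if (nrow(pairs) == 0L)
        notice <- paste0(.NO_PRIMER_NOTICE,
                         ": no pair satisfied the pairing constraints")
    }
  }
  result <- list(collection = coll, consensus = consensus, regions = regions,
                 feasibility = feas, candidates = candidates, pairs = pairs,
                 approach = approach, notice = notice, settings = settings)
  class(result) <- "design_result"
  if (!is.null(out))
    write_report(out, candidates = candidates, pairs = pairs,
                 consensus = consensus, regions = regions,
                 settings = settings, notice = notice)
  result
}

.read_any <- function(path, aligned = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^CLUSTAL", toupper(first))) read_clustal(path)
  else read_fasta(path, aligned = aligned)
}

#' @export
print.design_result <- function(x, ...) {
  cat("Primer design (", x$approach, " approach)\n", sep = "")
  cat("Template:", length(x$consensus$codes), "columns;",
      nrow(x$regions), "conserved region(s)\n")
  cat("Candidates:", nrow(x$candidates$forward), "forward,",
      nrow(x$candidates$reverse), "reverse\n")
  if (!is.null(x$notice)) {
    cat("Notice:", x$notice, "\n")
    if (nrow(x$pairs) == 0L) print(x$consensus)
  }
  if (nrow(x$pairs)) {
    cat("Optimized pairs:\n")
    print(x$pairs[, c("pair", "forward", "fwd_start", "reverse", "rev_start",
                      "amplicon_len", "tm_diff", "annealing_tm", "penalty")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate primers against every filter (test mode)
#'
#' Runs [evaluate_primer()] on each supplied primer and tabulates the
#' outcomes with the report vocabulary (Degeneracy, Deletions, GC content,
#' Repeats, Comp. ends, Size, Temp).
#'
#' @param primers Character vector of primer strings.
#' @param settings [primer_settings()].
#' @return An object of class `test_result`: list with `summary` (data frame:
#'   `primer`, `pass`, `filters_failed`, `tm_mean`, `penalty`) and `reports`
#'   (list of `filter_report`). Primers with invalid alphabet get an error
#'   row and a `NULL` report.
#' @export
run_test_mode <- function(primers, settings = primer_settings()) {
  stopifnot(length(primers) >= 1L)
  reports <- vector("list", length(primers))
  rows <- vector("list", length(primers))
  for (i in seq_along(primers)) {
    rep_i <- tryCatch(evaluate_primer(primers[[i]], settings),
                      error = function(e) e)
    if (inherits(rep_i, "error")) {
      rows[[i]] <- data.frame(primer = toupper(primers[[i]]), pass = NA,
                              filters_failed = paste("error:",
                                                     conditionMessage(rep_i)),
                              tm_mean = NA_real_, penalty = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      reports[[i]] <- rep_i
      rows[[i]] <- data.frame(
        primer = rep_i$primer, pass = !rep_i$failed,
        filters_failed = paste(failed_filters(rep_i), collapse = ", "),
        tm_mean = if (is.null(rep_i$tm)) NA_real_ else rep_i$tm[["mean"]],
        penalty = rep_i$penalty, stringsAsFactors = FALSE)
    }
  }
  out <- list(summary = do.call(rbind, rows), reports = reports)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  df <- x$summary
  df$tm_mean <- round(df$tm_mean, 1)
  print(df, row.names = FALSE)
  n_ok <- sum(df$pass, na.rm = TRUE)
  cat(sprintf("Passed: %d / %d (%.0f%%)\n", n_ok, nrow(df),
              100 * n_ok / nrow(df)))
  invisible(x)
}

#' Bundled example primer sets
#'
#' Two small evaluation fixtures shipped with the package: degenerate primer
#' sets targeting the iron-nitrogenase gene anfD produced by a reference-
#' guided web design tool, and concrete primer sets for the nitrogenase genes
#' anfD, nifK and vnfD produced by a consensus-plus-Primer3 pipeline. Both
#' are published third-party designs used to exercise test mode.
#'
#' @return Named list of data frames (`anfd_degenerate`,
#'   `nitrogenase_consensus`), each with `set`, `orientation`/`gene` and
#'   `sequence` columns.
#' @export
bundled_primer_sets <- function() {
  read1 <- function(f) utils::read.delim(
    system.file("extdata", f, package = "degenpcr"),
    comment.char = "#", stringsAsFactors = FALSE)
  list(anfd_degenerate = read1("primers_anfD_degenerate.tsv"),
       nitrogenase_consensus = read1("primers_nitrogenase_consensus.tsv"))
}
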