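# Synthetic alignment generator -----------------------------------------------

# Run code with a locally seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic MSA with planted conserved blocks
#'
#' Manufactures an aligned collection in which the columns inside
#' `conserved_blocks` are identical across sequences while every other column
#' is independently substituted (to a different base) with probability
#' `divergence_rate` and gapped with probability `gap_rate` per sequence.
#' The generator emulates a set of homologous gene sequences whose primer-
#' hosting sites are perfectly conserved; it is deterministic under `seed`.
#'
#' @param n_seqs Number of sequences (default 5).
#' @param length Alignment length in columns (default 400).
#' @param conserved_blocks List of `c(start, len)` 0-based blocks; must be
#'   disjoint and inside `[0, length)`.
#' @param divergence_rate Per-column, per-sequence substitution probability
#'   outside the blocks (default 0.2).
#' @param gap_rate Per-column, per-sequence deletion probability outside the
#'   blocks (default 0.02).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param template Optional template string of length `length`; random
#'   uniform A/C/G/T when `NULL`.
#' @return An aligned [seq_collection()] with the template stored in
#'   `attr(, "template")` and the blocks in `attr(, "blocks")`.
#' @export
generate_fixture_msa <- function(n_seqs = 5, length = 400,
                                 conserved_blocks = list(c(60, 40), c(260, 40)),
                                 divergence_rate = 0.2, gap_rate = 0.02,
                                 seed = NULL, template = NULL) {
  stopifnot(n_seqs >= 1, length >= 1)
  blocks <- do.call(rbind, lapply(conserved_blocks, function(b) {
    stopifnot(length(b) == 2L, b[1L] >= 0, b[2L] >= 1,
              b[1L] + b[2L] <= length)
    data.frame(start = b[1L], end = b[1L] + b[2L])
  }))
  if (!is.null(blocks) && nrow(blocks) > 1L) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (any(blocks$start[-1L] < blocks$end[-nrow(blocks)]))
      stop("conserved blocks overlap", call. = FALSE)
  }
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    tmpl <- if (is.null(template)) sample(bases, length, replace = TRUE)
            else .chars(normalize_sequence(template))
    stopifnot(base::length(tmpl) == length)
    inside <- logical(length)
    if (!is.null(blocks))
      for (i in seq_len(nrow(blocks)))
        inside[(blocks$start[i] + 1L):blocks$end[i]] <- TRUE
    seqs <- vapply(seq_len(n_seqs), function(s) {
      chars <- tmpl
      free <- which(!inside)
      mut <- free[stats::runif(base::length(free)) < divergence_rate]
      for (i in mut)
        chars[i] <- sample(setdiff(bases, chars[i]), 1L)
      gaps <- free[stats::runif(base::length(free)) < gap_rate]
      chars[gaps] <- .IUPAC_GAP
      paste(chars, collapse = "")
    }, "")
    names(seqs) <- paste0("seq_", seq_len(n_seqs))
    coll <- seq_collection(seqs, aligned = TRUE)
    attr(coll, "template") <- paste(tmpl, collapse = "")
    attr(coll, "blocks") <- blocks
    coll
  })
}
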