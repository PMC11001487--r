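# Independent oracles, deliberately implemented apart from the package code.

# Reverse complement via an explicit hand-typed code map.
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N", "-" = "-")
  chars <- strsplit(toupper(x), "")[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# Cartesian-product expansion from a hand-typed base-set table.
oracle_expand <- function(x) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(x), "")[[1]]
  chars <- chars[chars != "-"]
  grid <- expand.grid(lapply(chars, function(ch) sets[[ch]]),
                      stringsAsFactors = FALSE)
  sort(unique(apply(grid, 1, paste, collapse = "")))
}

# Second, independently typed copy of the unified stack parameters.
oracle_nn <- list(
  AA = c(-7.9, -22.2), TT = c(-7.9, -22.2), AT = c(-7.2, -20.4),
  TA = c(-7.2, -21.3), CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
  GT = c(-8.4, -22.4), AC = c(-8.4, -22.4), CT = c(-7.8, -21.0),
  AG = c(-7.8, -21.0), GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
  CG = c(-10.6, -27.2), GC = c(-9.8, -24.4), GG = c(-8.0, -19.9),
  CC = c(-8.0, -19.9))

oracle_nn_sums <- function(s) {
  b <- strsplit(s, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(b) - 1)) {
    p <- oracle_nn[[paste0(b[i], b[i + 1])]]
    dH <- dH + p[1]; dS <- dS + p[2]
  }
  for (e in b[c(1, length(b))]) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  if (identical(b, rev(unname(c(A = "T", C = "G", G = "C", T = "A")[b]))))
    dS <- dS - 1.4
  c(dH = dH, dS = dS)
}

# Hand-summed two-state melting temperature, salt term in the denominator.
oracle_tm <- function(s, monovalent = 0.05, ct = 50e-9, b_div = 4) {
  v <- oracle_nn_sums(s)
  chars <- strsplit(s, "")[[1]]
  selfc <- identical(chars,
                     rev(unname(c(A = "T", C = "G", G = "C", T = "A")[chars])))
  b <- if (selfc) 1 else b_div
  1000 * v[["dH"]] /
    (v[["dS"]] + 16.6 * log10(monovalent) + 1.9872 * log(ct / b)) - 273.15
}

oracle_dg <- function(s) {
  v <- oracle_nn_sums(s)
  unname(v[["dH"]] - 310.15 * v[["dS"]] / 1000)
}

# Run-length scan for maximal conserved runs (regex-free independent path).
oracle_regions <- function(codes, min_len) {
  conserved <- codes %in% c("A", "C", "G", "T")
  out <- NULL
  i <- 1
  n <- length(codes)
  while (i <= n) {
    if (conserved[i]) {
      j <- i
      while (j < n && conserved[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len)
        out <- rbind(out, data.frame(start = i - 1, end = j, length = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    data.frame(start = integer(), end = integer(), length = integer())
  else out
}

# Non-overlapping tandem-duplication tally, written as a regex-based scan.
oracle_tandem <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  hits <- 0
  i <- 1
  while (i + 2 * k - 1 <= length(chars)) {
    a <- paste(chars[i:(i + k - 1)], collapse = "")
    b <- paste(chars[(i + k):(i + 2 * k - 1)], collapse = "")
    if (a == b) { hits <- hits + 1; i <- i + 2 * k } else i <- i + 1
  }
  hits
}

# Brute-force pair selection: full cross-product, combined-penalty order,
# greedy uniqueness, independent re-check of every constraint.
oracle_pair_ok <- function(f, r, settings, codes) {
  amplicon <- (r$start + r$length) - f$start
  if (f$start + f$length > r$start) return(FALSE)
  if (amplicon < settings$min_amplicon) return(FALSE)
  if (abs(f$tm_mean - r$tm_mean) > settings$max_tm_diff + 1e-9) return(FALSE)
  slice <- codes[(f$start + 1):(r$start + r$length)]
  slice <- slice[slice != "-"]
  gc_sets <- list(A = 0, C = 1, G = 1, T = 0, R = .5, Y = .5, S = 1, W = 0,
                  K = .5, M = .5, B = 2/3, D = 1/3, H = 1/3, V = 2/3, N = .5)
  gc_pct <- 100 * mean(unlist(gc_sets[slice]))
  prod_tm <- 81.5 + 0.41 * gc_pct + 16.6 * log10(settings$monovalent) -
    675 / length(slice)
  ta <- 0.3 * min(f$tm_mean, r$tm_mean) + 0.7 * prod_tm - 14.9
  max(abs(f$tm_mean - ta), abs(r$tm_mean - ta)) <=
    settings$max_annealing_diff + 1e-9
}

oracle_pairs <- function(forward, reverse, settings, codes) {
  nf <- nrow(forward); nr <- nrow(reverse)
  grid <- expand.grid(fi = seq_len(nf), ri = seq_len(nr))
  grid$pen <- forward$penalty[grid$fi] + reverse$penalty[grid$ri]
  grid <- grid[order(grid$pen, grid$fi, grid$ri), ]
  used_f <- character(); used_r <- character()
  out <- NULL
  for (k in seq_len(nrow(grid))) {
    f <- forward[grid$fi[k], ]; r <- reverse[grid$ri[k], ]
    if (f$sequence %in% used_f || r$sequence %in% used_r) next
    if (!oracle_pair_ok(f, r, settings, codes)) next
    out <- rbind(out, data.frame(forward = f$sequence, reverse = r$sequence,
                                 penalty = f$penalty + r$penalty,
                                 stringsAsFactors = FALSE))
    used_f <- c(used_f, f$sequence); used_r <- c(used_r, r$sequence)
    if (nrow(out) >= settings$max_pairs) break
  }
  out
}

random_primer <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
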