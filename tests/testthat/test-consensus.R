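make_coll <- function(seqs) seq_collection(seqs, aligned = TRUE)

test_that("profiles tally columns and expose the reverse-strand view", {
  coll <- make_coll(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  prof <- build_profiles(coll)
  df <- as.data.frame(prof)
  expect_equal(df$top_ratio, rep(1, 4))
  expect_equal(df$top_base, c("A", "C", "G", "T"))
  coll2 <- make_coll(c(a = "A-", b = "A-", c = "T-"))
  df2 <- as.data.frame(build_profiles(coll2))
  expect_equal(df2$top_base[1], "A")
  expect_equal(df2$top_ratio[1], 2 / 3)
  expect_equal(df2$gap[2], 3)
  rev <- as.data.frame(reverse_profiles(build_profiles(coll)))
  expect_equal(rev$top_base, c("A", "C", "G", "T"))  # revcomp of ACGT
})

test_that("profile counts equal brute-force per-column tallies", {
  set.seed(401)
  seqs <- vapply(1:10, function(i) random_primer(50), "")
  names(seqs) <- paste0("s", 1:10)
  prof <- build_profiles(make_coll(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (b in c("A", "C", "G", "T")) {
    expect_equal(unname(prof$counts[b, ]),
                 vapply(seq_len(50), function(j) sum(mat[, j] == b), 0))
  }
  expect_equal(unname(colSums(prof$counts)), rep(10, 50))
})

test_that("unaligned input is a contract violation", {
  coll <- seq_collection(c(a = "ACGT", b = "ACGTA"), aligned = FALSE)
  expect_error(build_profiles(coll), "aligned")
})

test_that("consensus codes follow the majority/minor/gap thresholds", {
  cons_of <- function(seqs, ...) {
    consensus_string(assign_consensus(build_profiles(make_coll(seqs)), ...))
  }
  expect_equal(cons_of(c(a = "A", b = "A", c = "A", d = "A")), "A")
  expect_equal(cons_of(c(a = "A", b = "A", c = "G", d = "G")), "R")
  # 40% A / 35% C / 25% T with minor threshold 0.2: smallest cover is H
  seqs <- c(rep("A", 8), rep("C", 7), rep("T", 5))
  names(seqs) <- paste0("s", seq_along(seqs))
  expect_equal(cons_of(seqs, minor_threshold = 0.2), "H")
  # gap-dominated column becomes a deletion mark
  expect_equal(cons_of(c(a = "-", b = "-", c = "A", d = "C")), "-")
  # majority call at the 0.9 boundary
  seqs2 <- c(rep("A", 9), "G"); names(seqs2) <- paste0("s", 1:10)
  expect_equal(cons_of(seqs2), "A")
  seqs3 <- c(rep("A", 8), "G", "G"); names(seqs3) <- paste0("s", 1:10)
  expect_equal(cons_of(seqs3), "R")
})

test_that("consensus is invariant under sequence order and exact for
           identical sequences", {
  set.seed(402)
  seqs <- vapply(1:6, function(i) random_primer(40), "")
  names(seqs) <- paste0("s", 1:6)
  c1 <- assign_consensus(build_profiles(make_coll(seqs)))
  c2 <- assign_consensus(build_profiles(make_coll(sample(seqs))))
  expect_identical(c1$codes, c2$codes)
  same <- rep(seqs[1], 5); names(same) <- paste0("t", 1:5)
  cs <- consensus_string(assign_consensus(build_profiles(make_coll(same))))
  expect_identical(cs, unname(seqs[1]))
  expect_equal(degeneracy(cs), 1)
})

test_that("conserved regions are the maximal qualifying runs", {
  fully <- strrep("ACGTAC", 10)  # 60 conserved columns
  r <- find_conserved_regions(fully, min_len = 18)
  expect_equal(r, data.frame(start = 0L, end = 60L, length = 60L))
  split <- paste0(strrep("A", 20), "R", strrep("C", 20))
  r2 <- find_conserved_regions(split, min_len = 18)
  expect_equal(r2$start, c(0, 21))
  expect_equal(r2$end, c(20, 41))
  expect_equal(nrow(find_conserved_regions(split, min_len = 21)), 0)
})

test_that("random degenerate masks match the run-length oracle", {
  set.seed(403)
  codes_all <- c("A", "C", "G", "T", "R", "Y", "N", "-")
  for (i in 1:1000) {
    codes <- sample(codes_all, 60, replace = TRUE,
                    prob = c(rep(0.22, 4), rep(0.03, 4)))
    min_len <- sample(c(3, 8, 18), 1)
    got <- find_conserved_regions(paste(codes, collapse = ""), min_len)
    want <- oracle_regions(codes, min_len)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # regions are disjoint, ordered and within bounds
    if (nrow(got) > 1) expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    expect_lte(sum(got$length), 60)
  }
})

test_that("amplicon feasibility reflects the largest conserved span", {
  one <- data.frame(start = 0L, end = 200L, length = 200L)
  expect_true(check_amplicon_feasibility(one, 100, 300)$feasible)
  two <- data.frame(start = c(0L, 48L), end = c(18L, 66L),
                    length = c(18L, 18L))
  f <- check_amplicon_feasibility(two, 100, 300)
  expect_false(f$feasible)
  expect_equal(f$max_span, 66)
  none <- find_conserved_regions(strrep("N", 50), 18)
  expect_false(check_amplicon_feasibility(none, 100, 50)$feasible)
  expect_error(check_amplicon_feasibility(one, 20, 300), "twice")
})
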