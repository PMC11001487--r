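test_that("degeneracy filter enforces terminal trimers and the fold budget", {
  expect_false(filter_degeneracy("WGCACGCCGTGRTSAAGGGC")$pass)  # W leads
  expect_true(filter_degeneracy("ACGTACGTACGTACGTAA")$pass)
  # one 3-fold plus one 2-fold, none terminal: inside the stated limits
  expect_true(filter_degeneracy("ACGHACGTACGSACGTAAGC")$pass)
  expect_false(filter_degeneracy("ACGNACGTACGTACGTAAGC")$pass)   # any N
  expect_false(filter_degeneracy("ACGHACGHACGTACGTAAGC")$pass)   # two 3-folds
  expect_false(filter_degeneracy("ACGRACGSACGWACGTAAGC")$pass)   # three 2-folds
  expect_true(filter_degeneracy("ACGRACGSACGTACGTAAGC")$pass)    # two is fine
  expect_false(filter_degeneracy("ACGTACGTACGTACGTARG")$pass)    # 3' trimer
})

test_that("deletion filter applies its four rules to consensus windows", {
  s <- primer_settings()
  expect_false(filter_deletions("A-CGTACGTACGTACGTACG", s)$pass)  # terminal
  expect_false(filter_deletions("ACGTACGTAC----GTACGTACGT", s)$pass) # 4 run
  expect_true(filter_deletions("ACGTACGTAC---GTACGTACGTA", s)$pass)  # 3 run ok
  seven <- "ACGT-AC-GT-AC-GT-AC-GT-ACGTACGT"
  expect_false(filter_deletions(seven, s)$pass)                  # 7 total
  # rule iv: deletions push the gap-free length under the minimum
  expect_false(filter_deletions("ACGTA-CG-TA-CG-TA-CGTA", s)$pass)  # 17 left
  expect_true(filter_deletions("ACGTAC-CG-TA-CG-TACGTA", s)$pass)   # 18 left
  # a gapless short primer is the size filter's concern, not a deletion fail
  expect_true(filter_deletions("ACGTACGTACGTACGTA", s)$pass)
})

test_that("deletion rules agree with an enumerated gap-placement oracle", {
  s <- primer_settings()
  base <- strsplit("ACGTTGCAACGGTCTTGCACAT", "")[[1]]  # 22 columns
  set.seed(301)
  for (i in 1:200) {
    n_gap <- sample(0:7, 1)
    pos <- sample(22, n_gap)
    w <- base
    w[pos] <- "-"
    gaps <- w == "-"
    expected <- !(any(gaps[c(1:3, 20:22)]) ||
                    any(rle(gaps)$lengths[rle(gaps)$values] > 3) ||
                    sum(gaps) > 6 ||
                    (any(gaps) && sum(!gaps) < 18))
    expect_identical(filter_deletions(paste(w, collapse = ""), s)$pass,
                     expected)
  }
})

test_that("GC filter enforces the 40-60% range inclusively and the 3' clamp", {
  expect_false(filter_gc("GTGCAGCGAGTGCATCCCGG")$pass)   # 70%
  expect_true(filter_gc("ATATATATATGCGCGCGCAT")$pass)    # exactly 40%
  expect_false(filter_gc("AAAAATTTTTAAAAAGCGCC")$pass)   # 3' G/C run of 5
  expect_true(filter_gc("GTACATGGGCTTCGAGG")$pass)       # 3' run of 2, 58.8%
  # boundary pair around the clamp at fixed 40% GC
  expect_true(filter_gc("GCGCATATATATATAGCGCT")$pass)   # 3' run 0
  expect_false(filter_gc("GCGCATATATATATTAGCGC")$pass)  # 3' run 4
})

test_that("tandem repeat filter matches its oracle and the stated budgets", {
  expect_false(filter_repeats("ATATATATATATATATAT")$pass)
  expect_true(filter_repeats("GGACTTCGAGAAGGTGATC")$pass)   # one GA-GA tandem
  expect_true(filter_repeats("AACAACAAGGTGAACCTGAT")$pass)  # one AAC-AAC
  expect_false(filter_repeats("ACGTACGTAAATTTACGGCA")$pass) # tandem 4-mer
  set.seed(302)
  s <- primer_settings()
  for (i in 1:300) {
    p <- random_primer(sample(18:24, 1), alphabet = c("A", "C", "G", "T"))
    counts <- vapply(2:4, function(k) oracle_tandem(p, k), 0)
    expected <- counts[1] <= 2 && counts[2] <= 1 && counts[3] == 0
    expect_identical(filter_repeats(p, s)$pass, expected)
  }
})

test_that("complementary-ends filter compares the two terminal trimers", {
  expect_false(filter_complementary_ends("GCGAGTGCATCCCGGAGCGC")$pass)
  expect_false(filter_complementary_ends("CTTCAGCAACATGGTGAAG")$pass)
  expect_true(filter_complementary_ends("AAAAAAAAAAAAAAAAAA")$pass)
  # an internal (non-terminal) complementary match does not disqualify
  expect_true(filter_complementary_ends("GACTTCGAGAAGGTGATCG")$pass)
  # degenerate ends fail when any expansion matches
  expect_false(filter_complementary_ends("CTTCAGCAACATGGTGARG")$pass)
})

test_that("size filter uses gap-free length with inclusive bounds", {
  expect_false(filter_size("GTACATGGGCTTCGAGG")$pass)          # 17
  expect_true(filter_size(strrep("ACGT", 5))$pass)             # 20
  expect_true(filter_size(paste0(strrep("AC", 9)))$pass)       # 18 boundary
  expect_false(filter_size(paste0(strrep("A", 31)))$pass)      # 31
  expect_true(filter_size(strrep("A", 30))$pass)
  expect_false(filter_size("ACG-TACGTACGTACGT-A")$pass)        # 17 gap-free
})

test_that("temperature window filter is inclusive and widens with settings", {
  open <- primer_settings(tm_min = 0, tm_max = 100)
  expect_true(filter_tm_range("CTTCCAGCTGAAGTACACC", open)$pass)
  expect_false(filter_tm_range("CTTCCAGCTGAAGTACACC")$pass)    # ~48 C < 50
  s <- "GGACTTCGAGAAGGTGATC"
  tm <- melting_temperature(s)[["mean"]]
  at_boundary <- primer_settings(tm_min = tm, tm_max = 65)
  expect_true(filter_tm_range(s, at_boundary)$pass)
})

test_that("hairpin penalty counts motif windows additively", {
  # triloop instance: complementary C..G flanks, G second, A second-to-last
  expect_equal(hairpin_penalty("CGAAG"), 1)
  expect_equal(hairpin_penalty("ACGTACGTACGTACGTAC"), 0)
  expect_equal(hairpin_penalty("CGAAGTTTTTCGAAG"), 2) # two disjoint windows
  # scan oracle: every 5-window and 6-window checked by hand rules
  set.seed(303)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:200) {
    p <- random_primer(20)
    chars <- strsplit(p, "")[[1]]
    hits <- 0
    for (j in 1:16) {
      w <- chars[j:(j + 4)]
      if (w[5] == comp[[w[1]]] && w[2] == "G" && w[4] == "A") hits <- hits + 1
    }
    for (j in 1:15) {
      w <- chars[j:(j + 5)]
      if (w[6] == comp[[w[1]]] && w[2] == "G" && w[5] == "A") hits <- hits + 1
    }
    expect_equal(hairpin_penalty(p), hits)
  }
})

test_that("3' dimerization penalty triggers strictly below -3 kcal/mol", {
  expect_equal(end_dimer_penalty("ACGTACGTACGTAGGTGG"), 1)
  expect_equal(end_dimer_penalty("ACGTACGTACGTAAATAT"), 0)
  expect_equal(oracle_dg("AATAT") > -3, TRUE)
  # boundary: equality does not penalize
  s <- primer_settings(dimer_dg_threshold = delta_g("GGTGG"))
  expect_equal(end_dimer_penalty("ACGTACGTACGTAGGTGG", s), 0)
})

test_that("filters are pure and order-independent; penalties accumulate", {
  p <- "WGCACGCCGTGRTSAAGGGC"
  r1 <- evaluate_primer(p)
  r2 <- evaluate_primer(p)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(failed_filters(r1), failed_filters(r2))
  expect_gte(r1$penalty, 0)
  # failed is the OR over hard outcomes regardless of evaluation order
  fails <- vapply(r1$outcomes, function(o) !o$pass, TRUE)
  expect_identical(r1$failed, any(fails))
})

test_that("evaluate_primer rejects empty and invalid input", {
  expect_error(evaluate_primer(""), "empty")
  expect_error(evaluate_primer("ACGTZ"), "invalid")
  expect_error(evaluate_primer("ACGU"), "uracil")
})
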