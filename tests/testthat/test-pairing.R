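# Candidate tables used by the pairing tests are built directly so the
# constraint logic can be exercised against arbitrary geometries.
fake_candidate <- function(seq, start, tm, penalty, length = nchar(seq)) {
  data.frame(sequence = seq, orientation = "forward", start = start,
             length = length, gap_free_length = length,
             degeneracy = 1, tm_min = tm, tm_mean = tm, tm_max = tm,
             penalty = penalty, stringsAsFactors = FALSE)
}

test_that("window enumeration counts follow the combinatorics", {
  cons <- strrep("ACGTTGCAACGGTCTTGCA", 10)  # concrete, 190 columns
  s <- primer_settings()
  one <- enumerate_candidates(substr(cons, 1, 18), range = NULL,
                              settings = s, mode = "filtration")
  # a single 18-column template admits exactly one window per orientation
  expect_lte(nrow(one$forward), 1)
  # count generated windows via a permissive settings object (no rejects):
  open <- primer_settings(tm_min = 0, tm_max = 100, gc_min = 0, gc_max = 1,
                          clamp_max_run = 30)
  region40 <- data.frame(start = 0L, end = 40L, length = 40L)
  cons40 <- substr(cons, 1, 40)
  cand <- enumerate_candidates(cons40, regions = region40,
                               settings = open, mode = "conserved")
  # still filtered by repeats/comp-ends; compare against a direct window scan
  expected <- 0L
  for (L in 18:30) for (st in 0:(40 - L)) {
    w <- substr(cons40, st + 1, st + L)
    ok <- filter_repeats(w, open)$pass && filter_complementary_ends(w, open)$pass
    if (ok) expected <- expected + 1L
  }
  expect_equal(nrow(cand$forward), expected)
  # the raw window count the scan explores is sum over L of (40 - L + 1)
  expect_equal(sum(vapply(18:30, function(L) 40 - L + 1, 0)), 221)
})

test_that("filtration range restricts candidate starts", {
  set.seed(601)
  cons <- random_primer(300)
  open <- primer_settings(tm_min = 0, tm_max = 100, gc_min = 0, gc_max = 1)
  cand <- enumerate_candidates(cons, range = c(100L, 160L),
                               settings = open, mode = "filtration")
  if (nrow(cand$forward)) {
    expect_true(all(cand$forward$start >= 100))
    expect_true(all(cand$forward$start + cand$forward$length <= 160))
  }
  expect_error(enumerate_candidates(cons, range = c(200L, 400L),
                                    settings = open, mode = "filtration"),
               "range")
})

test_that("ranking is stable, penalty-first, and permutation-invariant", {
  a <- fake_candidate(strrep("AC", 10), 5, 55, 2.0)
  b <- fake_candidate(strrep("AG", 10), 0, 55, 0.0)
  d <- fake_candidate(strrep("AT", 10), 9, 55, 0.0)
  ranked <- rank_candidates(rbind(a, b, d))
  expect_equal(ranked$sequence, c(b$sequence, d$sequence, a$sequence))
  expect_equal(ranked$rank, 1:3)
  set.seed(602)
  pool <- do.call(rbind, lapply(1:40, function(i)
    fake_candidate(random_primer(20), sample(200, 1),
                   50 + runif(1, 0, 10), sample(0:3, 1))))
  r1 <- rank_candidates(pool)
  r2 <- rank_candidates(pool[sample(nrow(pool)), ])
  expect_equal(r1$sequence, r2$sequence)
  expect_equal(r1$penalty, r2$penalty)
})

test_that("pair constraints re-derive amplicon, Tm gap and annealing checks", {
  set.seed(603)
  cons <- random_primer(400)
  s <- primer_settings()
  for (i in 1:300) {
    f <- fake_candidate(random_primer(20), sample(0:150, 1),
                        runif(1, 45, 60), 0)
    r <- fake_candidate(random_primer(20), sample(100:380, 1),
                        runif(1, 45, 60), 0, length = 20)
    r$start <- min(r$start, 380)
    chk <- pair_constraints(f, r, s, cons)
    expect_identical(chk$ok,
                     oracle_pair_ok(f, r, s, strsplit(cons, "")[[1]]))
    expect_equal(chk$amplicon_len, (r$start + r$length) - f$start)
  }
  # threshold instances
  f <- fake_candidate(strrep("AC", 10), 0, 55, 0)
  r <- fake_candidate(strrep("AG", 10), 100, 56.2, 0)
  expect_false(pair_constraints(f, r, s, cons)$ok)  # Tm gap 1.2 C
  r$tm_mean <- 55.5
  expect_gte(pair_constraints(f, r, s, cons)$amplicon_len, 100)
})

test_that("pair selection equals the brute-force oracle on random fixtures", {
  set.seed(604)
  s <- primer_settings(block_size = 37)  # several blocks per run
  for (trial in 1:8) {
    cons <- random_primer(400)
    nf <- sample(c(15, 40, 80), 1)
    nr <- sample(c(15, 40, 80), 1)
    forward <- do.call(rbind, lapply(seq_len(nf), function(i)
      fake_candidate(random_primer(20), sample(0:120, 1),
                     runif(1, 48, 58), sample(0:4, 1) + round(runif(1), 2))))
    reverse <- do.call(rbind, lapply(seq_len(nr), function(i)
      fake_candidate(random_primer(20), sample(150:380, 1),
                     runif(1, 48, 58), sample(0:4, 1) + round(runif(1), 2))))
    forward <- rank_candidates(forward)
    reverse <- rank_candidates(reverse)
    got <- pair_primers(forward, reverse, s, cons)
    want <- oracle_pairs(forward, reverse, s, strsplit(cons, "")[[1]])
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$forward, want$forward)
      expect_equal(got$reverse, want$reverse)
      expect_equal(got$penalty, want$penalty)
    }
    # every returned pair re-verified; uniqueness; cap at five
    expect_lte(nrow(got), s$max_pairs)
    expect_false(any(duplicated(got$forward)))
    expect_false(any(duplicated(got$reverse)))
    if (nrow(got)) {
      for (k in seq_len(nrow(got))) {
        f <- forward[forward$sequence == got$forward[k] &
                       forward$start == got$fwd_start[k], ][1, ]
        r <- reverse[reverse$sequence == got$reverse[k] &
                       reverse$start == got$rev_start[k], ][1, ]
        expect_true(oracle_pair_ok(f, r, s, strsplit(cons, "")[[1]]))
      }
    }
  }
})

test_that("pairing degenerate cases: empty lists and a single feasible combo", {
  s <- primer_settings()
  empty <- rank_candidates(fake_candidate("ACGTACGTACGTACGTAC", 0, 50, 0)[0, ])
  one_r <- rank_candidates(fake_candidate(strrep("AG", 10), 150, 55, 0))
  out <- pair_primers(empty, one_r, s, strrep("ACGT", 100))
  expect_equal(nrow(out), 0)
  f <- rank_candidates(fake_candidate(strrep("AC", 10), 0, 55, 0))
  got <- pair_primers(f, one_r, s, strrep("ACGT", 100))
  expect_equal(nrow(got), 1)
  expect_equal(got$amplicon_len, 170)
})

test_that("searching finds ranked candidates and falls back to test mode", {
  f <- rank_candidates(rbind(
    fake_candidate("ACGTTGCAACGGTCTTGCAT", 0, 55, 0),
    fake_candidate("TGCAACGGTCTTGCATTGCA", 4, 55, 1)))
  cand <- list(forward = f, reverse = f[0, ])
  hit <- search_primer("acgttgcaacggtcttgcat", cand, "forward")
  expect_true(hit$found)
  expect_equal(hit$rank, 1)
  miss <- search_primer("GTGCAGCGAGTGCATCCCGG", cand, "forward")
  expect_false(miss$found)
  expect_s3_class(miss$report, "filter_report")
  expect_true("GC content" %in% failed_filters(miss$report))
  expect_error(search_primer("ACGZ", cand, "forward"), "invalid")
})
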