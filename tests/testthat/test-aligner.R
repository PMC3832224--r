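test_that("seed index records k-mer positions and seed counts", {
  idx <- build_index("ACGTACGTACGT", k = 8)
  expect_identical(as.integer(seed_positions(idx, "ACGTACGT")), c(0L, 4L))
  expect_identical(seed_count(idx), 5)  # 12 - 8 + 1 forward seeds
  expect_error(build_index("", k = 11), "empty")
  expect_error(build_index("ACGTACGT", k = 4), "k must be")
  expect_error(build_index("ACGTACGT", k = 35), "k must be")
})

test_that("a 1 Mb random sequence indexes ~length - k + 1 forward seeds", {
  set.seed(41)
  n <- 1000000L
  idx <- build_index(rand_dna(n), k = 13)
  expect_equal(seed_count(idx), n - 13 + 1)
})

test_that("an exact substring aligns at 100% identity over its full length", {
  set.seed(42)
  subj <- rand_dna(5000)
  idx <- build_index(subj, k = 13)
  q <- substr(subj, 1001, 1100)
  h <- best_local_hit(q, idx, min_identity = 95, min_aln_len = 50)
  expect_true(h$found)
  expect_identical(h$strand, "+")
  expect_identical(c(h$sstart, h$send), c(1000L, 1100L))
  expect_identical(h$columns, 100L)
  expect_identical(h$identity, 100)
})

test_that("a 90%-identity read is rejected at the 95% cutoff", {
  set.seed(43)
  subj <- rand_dna(5000)
  idx <- build_index(subj, k = 13)
  q <- substr(subj, 2001, 2100)
  x <- strsplit(q, "")[[1]]
  pos <- seq(5, 95, by = 10)  # 10 interior scattered substitutions
  for (i in pos) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  h <- best_local_hit(paste(x, collapse = ""), idx,
                      min_identity = 95, min_aln_len = 50)
  expect_false(h$found)
})

test_that("reported identity tracks the true mutation load within 0.5 points", {
  set.seed(44)
  subj <- rand_dna(50000)
  idx <- build_index(subj, k = 13)
  n_reads <- 200
  truth_id <- reads <- numeric(n_reads)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    st <- sample(49900, 1)
    m <- mutate_dna(substr(subj, st, st + 99), rbinom(1, 100, 0.02))
    reads[i] <- m$seq
    truth_id[i] <- 100 * (100 - m$n) / 100
  }
  h <- best_local_hit(reads, idx, min_identity = 0, min_aln_len = 30)
  expect_true(all(h$found))
  expect_lt(abs(mean(h$identity) - mean(truth_id)), 0.5)
})

test_that("raising the identity threshold only removes hits", {
  set.seed(45)
  subj <- rand_dna(20000)
  idx <- build_index(subj, k = 13)
  reads <- vapply(1:100, function(i) {
    st <- sample(19900, 1)
    mutate_dna(substr(subj, st, st + 99), rbinom(1, 100, 0.03))$seq
  }, "")
  h95 <- best_local_hit(reads, idx, min_identity = 95, min_aln_len = 50)
  h97 <- best_local_hit(reads, idx, min_identity = 97, min_aln_len = 50)
  expect_true(all(which(h97$found) %in% which(h95$found)))
})

test_that("reverse-complementing a read flips strand but not the interval", {
  set.seed(46)
  subj <- rand_dna(10000)
  idx <- build_index(subj, k = 13)
  for (i in 1:20) {
    st <- sample(9900, 1)
    q <- mutate_dna(substr(subj, st, st + 99), 3)$seq
    qr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    h1 <- best_local_hit(q, idx, min_identity = 80, min_aln_len = 50)
    h2 <- best_local_hit(qr, idx, min_identity = 80, min_aln_len = 50)
    expect_identical(h1$sstart, h2$sstart)
    expect_identical(h1$send, h2$send)
    expect_identical(h1$identity, h2$identity)
    expect_false(h1$strand == h2$strand)
  }
})

test_that("seeded hits reproduce the exhaustive Smith-Waterman score", {
  set.seed(47)
  n_pairs <- 100
  eligible <- agree <- 0
  for (i in seq_len(n_pairs)) {
    a <- rand_dna(60)
    b <- if (i %% 2 == 0) rand_dna(60)
         else mutate_dna(a, rbinom(1, 60, sample(c(0.05, 0.1, 0.2), 1)))$seq
    idx <- build_index(b, k = 8)
    h <- best_local_hit(a, idx, min_identity = 0, min_aln_len = 1)
    if (!h$found) next  # no seed: documented miss class
    eligible <- eligible + 1
    if (h$score == sw_oracle_score(a, b)) agree <- agree + 1
  }
  expect_gt(eligible, 30)
  expect_gte(agree / eligible, 0.99)
})

test_that("BLAST-style tabular output has 12 columns and 1-based coordinates", {
  set.seed(48)
  subj <- rand_dna(2000)
  idx <- build_index(subj, k = 13)
  h <- best_local_hit(substr(subj, 501, 600), idx, 95, 50, query_id = "r1")
  f <- tempfile(fileext = ".tsv")
  write_blast6(h, f)
  row <- strsplit(readLines(f), "\t")[[1]]
  expect_length(row, 12L)
  expect_identical(row[1], "r1")
  expect_identical(as.integer(row[9]), 501L)
  expect_identical(as.integer(row[10]), 600L)
})
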