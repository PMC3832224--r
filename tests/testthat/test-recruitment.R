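test_that("an exact read is kept at 100% identity and covered once", {
  set.seed(61)
  g <- annotated_genome("g", rand_dna(20000))
  rs <- read_set("r1", substr(g$sequence, 5001, 5100))
  p <- recruit(rs, g)
  expect_identical(p$n_kept, 1L)
  expect_identical(p$hits$identity, 100)
  expect_identical(sum(p$coverage), 100L)
  expect_identical(sum(p$coverage[5001:5100]), 100L)
})

test_that("alignment-length boundary: 50 aligned bp kept, 49 dropped", {
  set.seed(62)
  g <- annotated_genome("g", rand_dna(20000))
  idx_pos <- 8001
  make_read <- function(len) {
    core <- substr(g$sequence, idx_pos, idx_pos + len - 1)
    ## pad with bases chosen to mismatch the genome continuation so the
    ## local alignment cannot extend past the core
    after <- strsplit(substr(g$sequence, idx_pos + len,
                             idx_pos + len + 10), "")[[1]]
    pad <- vapply(after, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "", USE.NAMES = FALSE)
    paste0(core, paste(pad, collapse = ""))
  }
  rs <- read_set(c("keep", "drop"), c(make_read(50), make_read(49)))
  p <- recruit(rs, g, mode = "abs_len", min_identity = 95, min_len = 50)
  expect_identical(p$hits$query, "keep")
  expect_identical(p$hits$columns, 50L)
})

test_that("identity boundary: exactly 95.0% kept, just below dropped", {
  set.seed(63)
  g <- annotated_genome("g", rand_dna(20000))
  sub_at <- function(q, pos) {
    x <- strsplit(q, "")[[1]]
    for (i in pos) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
  }
  ## 3 interior mismatches in 60 columns: 57/60 = 95.0% exactly
  keep <- sub_at(substr(g$sequence, 1001, 1060), c(15, 30, 45))
  ## 4 interior mismatches in 79 columns: 75/79 = 94.94%
  drop <- sub_at(substr(g$sequence, 3001, 3079), c(15, 30, 45, 60))
  p <- recruit(read_set(c("keep", "drop"), c(keep, drop)), g,
               min_identity = 95, min_len = 50)
  expect_identical(p$hits$query, "keep")
  expect_equal(p$hits$identity, 95)
})

test_that("frac_len mode scales the length cutoff with the read", {
  set.seed(64)
  g <- annotated_genome("g", rand_dna(20000))
  ## 100-bp read whose first 45 bp match: fails 50% of 100, passes 50 bp? no:
  ## abs_len also fails (45 < 50); a 90-bp read with 46 matching bp passes
  ## abs_len=45 but fails frac_len (46 < 45)? use clear-cut cases instead
  core <- substr(g$sequence, 2001, 2060)
  tail_junk <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  read120 <- paste0(core, tail_junk)  # aligns ~60 of 120 = 50%
  p_abs <- recruit(read_set("r", read120), g, mode = "abs_len",
                   min_identity = 95, min_len = 50)
  p_frac <- recruit(read_set("r", read120), g, mode = "frac_len",
                    min_identity = 95, frac_len = 0.7)
  expect_identical(p_abs$n_kept, 1L)   # 60 >= 50 bp
  expect_identical(p_frac$n_kept, 0L)  # 60 < 0.7 * 120
})

test_that("normalized recruitment follows the per-Mbp^2 formula exactly", {
  set.seed(65)
  g <- annotated_genome("g", rand_dna(50000))
  starts <- sample(49900, 200)
  rs <- read_set(paste0("r", 1:200),
                 substring(g$sequence, starts, starts + 99))
  p <- recruit(rs, g)
  expect_equal(p$normalized,
               p$n_kept / ((50000 / 1e6) * (200 * 100 / 1e6)))
  ## doubling the database with non-recruiting reads halves the value
  junk <- vapply(1:200, function(i) rand_dna(100), "")
  rs2 <- read_set(c(rs$ids, paste0("j", 1:200)), c(rs$sequences, junk))
  p2 <- recruit(rs2, g)
  expect_identical(p2$n_kept, p$n_kept)
  expect_equal(p2$normalized, p$normalized / 2)
})

test_that("kept set at (97%, 50bp) is a subset of the kept set at (95%, 50bp)", {
  set.seed(66)
  g <- annotated_genome("g", rand_dna(30000))
  reads <- vapply(1:150, function(i) {
    st <- sample(29900, 1)
    mutate_dna(substring(g$sequence, st, st + 99), rbinom(1, 100, 0.04))$seq
  }, "")
  rs <- read_set(paste0("r", 1:150), reads)
  k95 <- recruit(rs, g, min_identity = 95)$hits$query
  k97 <- recruit(rs, g, min_identity = 97)$hits$query
  expect_true(all(k97 %in% k95))
})

test_that("uniform coverage yields no island calls", {
  prof <- list(coverage = rep(10L, 60000), genome = "g")
  expect_identical(nrow(call_islands(prof)), 0L)
})

test_that("a zeroed 20-kb stretch is called as one island within 2 kb", {
  cov <- rep(10L, 100000)
  cov[15001:35000] <- 0L
  calls <- call_islands(list(coverage = cov, genome = "g"))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$label, "GI1")
  ## contained within +-2 kb of the stretch and covering >= 80% of it
  expect_gte(calls$start, 15000 - 2000)
  expect_lte(calls$end, 35000 + 2000)
  overlap <- min(calls$end, 35000) - max(calls$start, 15000)
  expect_gte(overlap / 20000, 0.8)
})

test_that("degenerate coverage profiles warn and return no calls", {
  expect_warning(c1 <- call_islands(list(coverage = rep(0L, 50000),
                                         genome = "g")), "all-zero")
  expect_identical(nrow(c1), 0L)
  ## mostly-zero profile: median window is zero, no-call rather than
  ## islands everywhere
  cov <- rep(0L, 50000); cov[1:2000] <- 5L
  expect_warning(c2 <- call_islands(list(coverage = cov, genome = "g")),
                 "median")
  expect_identical(nrow(c2), 0L)
})

test_that("island calls are invariant under read order permutation", {
  g <- generate_genome(120000, gc = 0.55, seed = 67, id = "perm")
  isl <- data.frame(start = 40000, end = 60000, frequency = 0)
  rs <- simulate_reads(island_community(g, isl, n_reads = 15000, seed = 68))
  perm <- sample(length(rs$ids))
  rs_shuf <- read_set(rs$ids[perm], rs$sequences[perm])
  p1 <- recruit(rs, g)
  p2 <- recruit(rs_shuf, g)
  expect_equal(p1$normalized, p2$normalized)
  expect_identical(call_islands(p1), call_islands(p2))
})

test_that("community recruitment splits exact ties fractionally", {
  set.seed(69)
  s <- rand_dna(20000)
  gA <- annotated_genome("A", s)
  gB <- annotated_genome("B", s)  # identical twin: every hit ties
  starts <- sample(19900, 50)
  rs <- read_set(paste0("r", 1:50), substring(s, starts, starts + 99))
  prof <- recruit_community(rs, list(gA, gB))
  expect_equal(prof$A$n_kept, 25)
  expect_equal(prof$B$n_kept, 25)
  expect_equal(prof$A$normalized, prof$B$normalized)
})
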