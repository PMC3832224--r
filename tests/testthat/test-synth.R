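test_that("generated genomes hit the target GC within a binomial bound", {
  g <- generate_genome(100000, gc = 0.63, mean_gene_len = 1000,
                       mean_spacer = 15, seed = 7)
  expect_lt(abs(gc_content(g) - 0.63), 0.01)
  expect_identical(g$length, 100000L)
})

test_that("generated spacer medians sit near the requested mean", {
  g <- generate_genome(100000, gc = 0.6, mean_spacer = 15, seed = 8)
  med <- intergenic_spacers(g)$median
  expect_gte(med, 10)
  expect_lte(med, 20)
})

test_that("generation is deterministic given the seed", {
  g1 <- generate_genome(30000, gc = 0.55, seed = 9)
  g2 <- generate_genome(30000, gc = 0.55, seed = 9)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  g3 <- generate_genome(30000, gc = 0.55, seed = 10)
  expect_false(g1$sequence == g3$sequence)
})

test_that("generated proteins are translations without internal stops", {
  g <- generate_genome(50000, gc = 0.6, seed = 11)
  expect_false(any(grepl("*", g$features$protein, fixed = TRUE)))
  f <- g$features[1, ]
  nt <- substr(g$sequence, f$start + 1, f$end)
  if (f$strand == "-") nt <- streamscan:::dna_revcomp(nt)
  expect_identical(streamscan:::translate_cds(nt), f$protein)
})

test_that("infeasible layouts are rejected", {
  expect_error(generate_genome(1000, gc = 0.5, mean_gene_len = 1000,
                               seed = 1), "smaller")
  expect_error(generate_genome(10000, gc = 1.2, seed = 1), "gc")
})

test_that("lineage mutation plants the stated substitution rate with a log", {
  g <- generate_genome(60000, gc = 0.6, seed = 12)
  m0 <- mutate_lineage(g, 0, seed = 13)
  expect_identical(m0$genome$sequence, g$sequence)
  expect_identical(nrow(m0$log), 0L)

  m <- mutate_lineage(g, 0.05, seed = 14)
  d <- hamming(g$sequence, m$genome$sequence)
  expect_identical(nrow(m$log), d)  # log records exactly the changes
  expect_lt(abs(d / g$length - 0.05), 0.003)
  ## log positions really differ and carry correct ref/alt
  i <- m$log[1, ]
  expect_identical(substr(g$sequence, i$pos + 1, i$pos + 1), i$ref)
  expect_identical(substr(m$genome$sequence, i$pos + 1, i$pos + 1), i$alt)
})

test_that("single-member communities label every read with the member", {
  g <- generate_genome(40000, gc = 0.55, seed = 15, id = "solo")
  rs <- simulate_reads(community_spec(list(list(genome = g, abundance = 1)),
                                      n_reads = 1000, seed = 16))
  expect_length(rs, 1000L)
  expect_true(all(rs$truth$genome == "solo"))
  expect_true(all(rs$truth$end - rs$truth$start == 100))
})

test_that("zero-frequency islands emit no reads from the island interval", {
  g <- generate_genome(100000, gc = 0.55, seed = 17)
  isl <- data.frame(start = 40000, end = 60000, frequency = 0)
  rs <- simulate_reads(island_community(g, isl, n_reads = 20000, seed = 18))
  tr <- rs$truth
  expect_false(any(tr$start < 60000 & tr$end > 40000))
  expect_false(any(tr$from_island))
})

test_that("read counts follow abundance x length weighting", {
  g1 <- generate_genome(50000, gc = 0.5, seed = 19, id = "major")
  g2 <- generate_genome(50000, gc = 0.5, seed = 20, id = "minor")
  spec <- community_spec(list(list(genome = g1, abundance = 0.8),
                              list(genome = g2, abundance = 0.2)),
                         n_reads = 100000, seed = 21)
  rs <- simulate_reads(spec)
  frac <- mean(rs$truth$genome == "major")
  expect_lt(abs(frac - 0.8), 0.01)
})

test_that("read simulation is deterministic and validates inputs", {
  g <- generate_genome(30000, gc = 0.5, seed = 22)
  spec <- community_spec(list(list(genome = g, abundance = 1)),
                         n_reads = 500, seed = 23)
  r1 <- simulate_reads(spec); r2 <- simulate_reads(spec)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$truth, r2$truth)
  expect_error(community_spec(list(list(genome = g, abundance = 0)),
                              seed = 1), "abundance")
  expect_error(community_spec(list(list(genome = g, abundance = 1)),
                              read_length = 100), "seed")
  long <- community_spec(list(list(genome = g, abundance = 1)),
                         read_length = 40000, n_reads = 10, seed = 2)
  expect_error(simulate_reads(long), "read length")
})

test_that("halophile proteomes carry the acidic composition shift", {
  p <- generate_proteome("halophile", n_proteins = 200, seed = 24)
  all_aa <- paste(p, collapse = "")
  de <- sum(strsplit(all_aa, "")[[1]] %in% c("D", "E")) / nchar(all_aa)
  expect_gte(de, 0.15)
  p2 <- generate_proteome("halophile", n_proteins = 200, seed = 24)
  expect_identical(p, p2)
})

test_that("lineage divergence feeds through to read identity", {
  g <- generate_genome(50000, gc = 0.6, seed = 25, id = "ref")
  spec <- community_spec(list(list(genome = g, abundance = 1,
                                   divergence = 0.05)),
                         n_reads = 400, error_rate = 0, seed = 26)
  rs <- simulate_reads(spec)
  p <- recruit(rs, g, min_identity = 0, min_len = 50)
  ## reads come from a 5%-diverged lineage: mean identity ~95
  expect_lt(abs(mean(p$hits$identity) - 95), 1)
})
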