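test_that("GC content matches hand-computable cases and excludes N", {
  expect_identical(gc_content("GGCC"), 1)
  expect_identical(gc_content("ATATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTNNNN"), 0.5)  # N out of the denominator
  expect_error(gc_content("NNNN"), "unambiguous")
})

test_that("GC content is invariant under complementation", {
  set.seed(21)
  for (i in 1:20) {
    s <- rand_dna(sample(50:500, 1))
    expect_equal(gc_content(streamscan:::dna_complement(s)), gc_content(s))
  }
})

test_that("spacer distribution follows the clamped-gap definition", {
  feats <- data.frame(start = c(0L, 24L, 30L), end = c(10L, 30L, 40L),
                      strand = "+", kind = "CDS", protein = NA)
  g <- annotated_genome("g", paste(rep("ACGT", 10), collapse = ""),
                        features = feats)
  sp <- intergenic_spacers(g)
  expect_identical(sp$spacers, c(14L, 0L))
  expect_equal(sp$median, 7)
})

test_that("overlapping features clamp to zero or are excluded by policy", {
  feats <- data.frame(start = c(0L, 7L, 30L), end = c(10L, 20L, 40L),
                      strand = "+", kind = "CDS", protein = NA)
  g <- annotated_genome("g", rand_dna(40), features = feats)
  expect_identical(intergenic_spacers(g, policy = "clamp")$spacers,
                   c(0L, 10L))
  expect_identical(intergenic_spacers(g, policy = "exclude")$spacers, 10L)
})

test_that("spacer list length is n_features - 1 and all spacers >= 0", {
  set.seed(22)
  for (i in 1:10) {
    g <- generate_genome(20000, gc = 0.5, mean_gene_len = 600,
                         mean_spacer = sample(5:60, 1), seed = 100 + i)
    sp <- intergenic_spacers(g)
    expect_length(sp$spacers, nrow(g$features) - 1L)
    expect_true(all(sp$spacers >= 0))
  }
})

test_that("fewer than two features yields an empty distribution with warning", {
  g <- annotated_genome("g", rand_dna(100),
                        features = data.frame(start = 0L, end = 30L,
                                              strand = "+", kind = "CDS",
                                              protein = NA))
  expect_warning(sp <- intergenic_spacers(g), "fewer than 2")
  expect_length(sp$spacers, 0L)
  expect_true(is.na(sp$median))
})

test_that("coding density uses interval union semantics", {
  n <- 100L
  seq <- strrep("ACGT", 25)
  whole <- annotated_genome("g", seq,
                            features = data.frame(start = 0L, end = n,
                                                  strand = "+", kind = "CDS",
                                                  protein = NA))
  expect_equal(coding_density(whole), 1)
  stacked <- annotated_genome("g", seq,
                              features = data.frame(start = c(0L, 0L),
                                                    end = c(50L, 50L),
                                                    strand = c("+", "-"),
                                                    kind = "CDS",
                                                    protein = NA))
  expect_equal(coding_density(stacked), 0.5)
})

test_that("coding density is invariant under reordering and duplication", {
  set.seed(23)
  feats <- data.frame(start = c(5L, 40L, 100L), end = c(35L, 80L, 160L),
                      strand = "+", kind = "CDS", protein = NA)
  s <- rand_dna(200)
  base <- coding_density(annotated_genome("g", s, features = feats))
  shuffled <- feats[c(3, 1, 2), ]
  duplicated <- rbind(feats, feats[2, ])
  expect_equal(coding_density(annotated_genome("g", s, features = shuffled)),
               base)
  expect_equal(coding_density(annotated_genome("g", s, features = duplicated)),
               base)
})

test_that("planted gene layouts are recovered exactly from synthetic genomes", {
  g <- generate_genome(50000, gc = 0.55, mean_gene_len = 800,
                       mean_spacer = 25, seed = 77)
  f <- g$features
  planted <- sum(f$end - f$start) / g$length  # generator never overlaps genes
  expect_equal(coding_density(g), planted)
  st <- genome_stats(g)
  expect_identical(st$cds_count, nrow(f))
  expect_equal(st$coding_density, planted)
  expect_equal(st$median_spacer, intergenic_spacers(g)$median)
})
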