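## Fixture builders shared across tests. Everything is generated in code;
## RNG use is always wrapped in a local seed so tests are order-independent.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## substitution mutation with an exact log (independent of the package's
## mutate_lineage, so it can serve as its oracle)
mutate_dna <- function(s, n_sub) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(x), n_sub)
  for (i in pos) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  list(seq = paste(x, collapse = ""), pos = sort(pos), n = n_sub)
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## independent exhaustive local-alignment score: best over both strands,
## same scoring scheme as the package aligner
sw_oracle_score <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  s1 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  s2 <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(query)),
    Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  max(s1, s2)
}

## minimal two-gene GenBank flat file used by the io tests
gb_fixture_text <- function() {
  c("LOCUS       TESTREC                 120 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "ACCESSION   TESTREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"synthetic construct\"",
    "     gene            1..30",
    "                     /locus_tag=\"t0001\"",
    "     CDS             1..30",
    "                     /locus_tag=\"t0001\"",
    "                     /translation=\"MKKLLPT",
    "                     AI\"",
    "     CDS             complement(41..70)",
    "                     /locus_tag=\"t0002\"",
    "     tRNA            75..100",
    "                     /product=\"tRNA-Xxx\"",
    "ORIGIN",
    paste0("        1 atgaaaaaac tgctgccgac cgcgatttaa tttttttttt",
           " ttacgcgcgc gcgcgcgcat"),
    paste0("       61 gcgcgcgcgc gcgcgcgcgt aaaaaaaaaa accccccccc",
           " ccccccgggg gggggggggg"),
    "//")
}

write_gb_fixture <- function(path = tempfile(fileext = ".gb")) {
  writeLines(gb_fixture_text(), path)
  path
}

## quick two-member community used by recruitment tests
island_community <- function(genome, islands, n_reads = 20000, seed = 5,
                             error_rate = 0.005) {
  community_spec(list(list(genome = genome, abundance = 1,
                           islands = islands)),
                 read_length = 100L, n_reads = n_reads,
                 error_rate = error_rate, seed = seed)
}
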