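`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed Mersenne-Twister seed, restoring the
## caller's RNG state afterwards. All stochastic entry points route through
## this so that (spec, seed) fully determines every synthetic data set.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

## DNA helpers on plain character strings (sequences are stored as single
## uppercase strings; Biostrings is used at I/O and translation boundaries).
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dna_complement <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAString(x)))
}

base_counts <- function(x) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(x))
  counts[c("A", "C", "G", "T", "N")]
}

## Translate a CDS nucleotide string (already on the coding strand) with the
## standard code; trailing stop removed; incomplete final codon dropped.
translate_cds <- function(nt) {
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  if (nchar(nt) < 3L) return("")
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt),
                          if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
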