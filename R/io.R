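#' Annotated genome container
#'
#' Bundles a DNA sequence with an ordered feature table. This is the common
#' substrate of the streamlining metrics, fragment recruitment and ANI
#' computations. All coordinates are 0-based half-open; GenBank and GFF3
#' coordinates (1-based inclusive) are converted on ingest. Circular
#' replicons are linearized at position 0 and treated as linear downstream;
#' features or alignments spanning the origin are not reconstructed.
#'
#' @param id genome identifier.
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive; stored
#'   uppercase).
#' @param features `data.frame` with columns `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `kind` (`"CDS"`, `"rRNA"`, `"tRNA"`,
#'   `"other"`) and `protein` (amino-acid string for CDS, otherwise `NA`).
#' @param topology `"linear"` or `"circular"`.
#'
#' @return An object of class `annotated_genome` with elements `id`,
#'   `sequence`, `features`, `topology` and `length`.
#' @examples
#' g <- annotated_genome("g1", "ATGAAATAGCCC",
#'   features = data.frame(start = 0, end = 9, strand = "+",
#'                         kind = "CDS", protein = "MK"))
#' g$length
#' @export
annotated_genome <- function(id, sequence,
                             features = empty_features(),
                             topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stopf("genome '%s': sequence length must be > 0", id)
  if (grepl("[^ACGTN]", sequence))
    stopf("genome '%s': sequence contains characters outside {A,C,G,T,N}", id)
  features <- as_feature_table(features)
  n <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 0 | features$end > n | features$start >= features$end
    if (any(bad))
      stopf("genome '%s': %d feature(s) with invalid interval (must satisfy 0 <= start < end <= %d)",
            id, sum(bad), n)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = as.character(id), sequence = sequence,
                 features = features, topology = topology, length = n),
            class = "annotated_genome")
}

empty_features <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             kind = character(), protein = character(),
             stringsAsFactors = FALSE)
}

as_feature_table <- function(features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!nrow(features)) return(empty_features())
  required <- c("start", "end")
  if (!all(required %in% names(features)))
    stop("feature table needs `start` and `end` columns", call. = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand %||% "+")
  features$kind <- as.character(features$kind %||% "other")
  if (is.null(features$protein)) features$protein <- NA_character_
  features$protein <- as.character(features$protein)
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  if (!all(features$kind %in% c("CDS", "rRNA", "tRNA", "other")))
    stop("feature kind must be one of CDS, rRNA, tRNA, other", call. = FALSE)
  features$protein[features$kind != "CDS"] <- NA_character_
  features[c("start", "end", "strand", "kind", "protein")]
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d features (%d CDS)\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features), sum(x$features$kind == "CDS")))
  invisible(x)
}

#' Read set container
#'
#' Holds metagenomic (or simulated) reads, optionally with a truth table
#' recording each read's source genome, source interval on that genome and
#' whether it overlaps a planted flexible island. Truth is filled by
#' [simulate_reads()] and consumed by the recovery checks.
#'
#' @param ids character vector of unique read ids.
#' @param sequences DNA strings, same length as `ids`.
#' @param truth optional `data.frame` with columns `read`, `genome`, `start`,
#'   `end`, `from_island`; `truth$read` must be a subset of `ids`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(ids, sequences, truth = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` lengths differ", call. = FALSE)
  if (anyDuplicated(ids)) stop("read ids must be unique", call. = FALSE)
  if (!is.null(truth)) {
    truth <- as.data.frame(truth, stringsAsFactors = FALSE)
    if (!all(truth$read %in% ids))
      stop("truth table refers to unknown read ids", call. = FALSE)
  }
  structure(list(ids = ids, sequences = sequences, truth = truth),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s\n", length(x$ids),
              if (is.null(x$truth)) "" else " (truth-labelled)"))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$ids)

#' Read a genome with its annotation
#'
#' @param path path to the sequence file (FASTA or GenBank flat file).
#' @param format `"fasta"` (no features), `"genbank"`, or `"fasta+gff3"`
#'   (supply the annotation through `gff3`).
#' @param gff3 path to a GFF3 file when `format = "fasta+gff3"`.
#' @param id override the record id.
#' @return An [annotated_genome()]. GenBank CDS `/translation` qualifiers are
#'   kept when present; otherwise (and for GFF3 CDS) proteins are translated
#'   from the genome with the standard code, trailing stop removed.
#' @export
read_genome <- function(path, format = c("fasta", "genbank", "fasta+gff3"),
                        gff3 = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank(path, id = id))
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stopf("no FASTA records in '%s'", path)
  if (length(seqs) > 1L)
    warnf("'%s' has %d records; using the first", path, length(seqs))
  rec_id <- id %||% sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  if (format == "fasta")
    return(annotated_genome(rec_id, sequence))
  if (is.null(gff3)) stop("format 'fasta+gff3' needs a `gff3` path", call. = FALSE)
  feats <- read_gff3_features(gff3, sequence)
  annotated_genome(rec_id, sequence, features = feats)
}

## GFF3 -> internal feature table; coordinates converted from 1-based
## inclusive to 0-based half-open. CDS proteins translated from sequence.
read_gff3_features <- function(path, sequence) {
  gr <- rtracklayer::import.gff3(path)
  if (length(gr) == 0L) return(empty_features())
  type <- as.character(gr$type)
  kind <- ifelse(type == "CDS", "CDS",
          ifelse(type == "rRNA", "rRNA",
          ifelse(type == "tRNA", "tRNA", "other")))
  keep <- type != "region"
  gr <- gr[keep]; kind <- kind[keep]
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  protein <- rep(NA_character_, length(gr))
  is_cds <- kind == "CDS"
  if (any(is_cds)) {
    protein[is_cds] <- vapply(which(is_cds), function(i) {
      nt <- substr(sequence, start0[i] + 1L, end0[i])
      if (strand[i] == "-") nt <- dna_revcomp(nt)
      translate_cds(nt)
    }, character(1))
  }
  data.frame(start = start0, end = end0, strand = strand, kind = kind,
             protein = protein, stringsAsFactors = FALSE)
}

#' Read metagenomic reads
#'
#' @param path FASTA or FASTQ file (qualities are ignored).
#' @param format `"fasta"` or `"fastq"`.
#' @return A [read_set()] without truth labels.
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  read_set(sub("\\s.*$", "", names(seqs)), as.character(seqs))
}

#' Write reads as FASTA
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  x <- Biostrings::DNAStringSet(reads$sequences)
  names(x) <- reads$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a genome as FASTA (and optionally GFF3)
#'
#' @param genome an [annotated_genome()].
#' @param path FASTA output path.
#' @param gff3 optional GFF3 output path for the feature table.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, gff3 = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  if (!is.null(gff3)) {
    f <- genome$features
    lines <- "##gff-version 3"
    if (nrow(f)) {
      type <- ifelse(f$kind %in% c("CDS", "rRNA", "tRNA"), f$kind, "gene")
      lines <- c(lines, sprintf("%s\tstreamscan\t%s\t%d\t%d\t.\t%s\t%s\tID=feat%d",
                                genome$id, type, f$start + 1L, f$end,
                                f$strand, ifelse(type == "CDS", "0", "."),
                                seq_len(nrow(f))))
    }
    writeLines(lines, gff3)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention, so intervals
#' are written verbatim. An empty interval set yields an empty file.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as.data.frame(intervals)
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  if (!all(c("chrom", "start", "end") %in% cols))
    stop("`intervals` needs chrom/start/end columns", call. = FALSE)
  write.table(intervals[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name` (0-based half-open coordinates, as in the file).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x
}

#' Write a table as TSV with a header row
#'
#' @param table `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
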