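#' Build a seed index over a subject sequence
#'
#' Exact k-mer position index used by [best_local_hit()]. Queries are
#' searched on both strands against the index, so reverse-complement hits
#' are reported with strand `"-"`.
#'
#' @param subject DNA string or [annotated_genome()].
#' @param k seed length, `8 <= k <= 31` (defaults: 13 for read recruitment,
#'   11 for ANI fragments).
#' @return An object of class `seed_index`.
#' @export
build_index <- function(subject, k = 13L) {
  id <- "subject"
  if (inherits(subject, "annotated_genome")) {
    id <- subject$id
    subject <- subject$sequence
  }
  ptr <- .cpp_build_index(toupper(as.character(subject)), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), subject_id = id,
                 subject_length = nchar(subject)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  info <- .cpp_index_info(x$ptr)
  cat(sprintf("<seed_index> %s: %s bp, k=%d, %s seeds (%s distinct)\n",
              x$subject_id, format(info$length, big.mark = ","), info$k,
              format(info$n_seeds, big.mark = ","),
              format(info$n_distinct, big.mark = ",")))
  invisible(x)
}

#' Number of (forward) seeds in an index
#' @param index a [build_index()] result.
#' @return seed count.
#' @export
seed_count <- function(index) .cpp_index_info(index$ptr)$n_seeds

#' Positions of one k-mer in the index
#' @param index a [build_index()] result.
#' @param kmer k-mer string of length `k`.
#' @return 0-based start positions on the subject forward strand.
#' @export
seed_positions <- function(index, kmer) .cpp_seed_positions(index$ptr, kmer)

## Shared scoring scheme: match +1, mismatch -2, gap of length L costs
## gap_open + L * gap_ext. Percent identity = matches / alignment columns
## (gap columns included in the denominator). N columns never match.
default_scoring <- function() {
  list(match = 1L, mismatch = -2L, gap_open = 5L, gap_ext = 2L,
       band = 32L, max_clusters = 10L)
}

#' Best local alignment of queries against an indexed subject
#'
#' Seed-and-extend: exact k-mer seeds are grouped per diagonal band and a
#' banded affine-gap Smith-Waterman extension is run around each band on
#' both strands; the highest-scoring alignment meeting both thresholds is
#' returned per query (ties: lower subject start, then forward strand).
#' Queries with no seed match, or no alignment passing the thresholds, get
#' `found = FALSE` -- absence of a hit is a value, not an error.
#'
#' @param query DNA string(s).
#' @param index a [build_index()] result.
#' @param min_identity minimum percent identity (0-100).
#' @param min_aln_len minimum alignment length in columns; scalar or one
#'   value per query.
#' @param scoring scoring parameters, see `default_scoring` values in the
#'   description.
#' @param query_id optional query names for the output.
#' @return `data.frame` (one row per query): `query`, `found`, `strand`,
#'   `sstart`, `send` (subject interval, 0-based half-open), `qstart`,
#'   `qend`, `matches`, `columns`, `score`, `identity` (percent).
#' @examples
#' idx <- build_index("ACGTACGTACGT", k = 8)
#' best_local_hit("ACGTACGT", idx, min_identity = 0, min_aln_len = 8)
#' @export
best_local_hit <- function(query, index, min_identity = 95,
                           min_aln_len = 50L, scoring = default_scoring(),
                           query_id = NULL) {
  stopifnot(inherits(index, "seed_index"))
  query <- toupper(as.character(query))
  if (any(nchar(query) < index$k))
    stopf("all queries must be at least k=%d bp", index$k)
  min_cols <- as.integer(min_aln_len)
  if (!length(min_cols) %in% c(1L, length(query)))
    stop("`min_aln_len` must be scalar or one value per query", call. = FALSE)
  res <- .cpp_best_hits(query, index$ptr, as.numeric(min_identity), min_cols,
                        scoring$band, scoring$max_clusters, scoring$match,
                        scoring$mismatch, scoring$gap_open, scoring$gap_ext,
                        TRUE)
  out <- as.data.frame(res, stringsAsFactors = FALSE)
  out <- cbind(query = query_id %||% paste0("q", seq_along(query)), out,
               stringsAsFactors = FALSE)
  out$subject <- index$subject_id
  out
}

#' Write alignment hits in BLAST tabular (outfmt 6) layout
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap columns, qstart, qend, sstart, send (these four 1-based inclusive, as
#' BLAST prints them; minus-strand hits have sstart > send), and two
#' placeholder columns (evalue, bitscore) filled with `NA` and the raw
#' score.
#'
#' @param hits a [best_local_hit()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(hits, path) {
  h <- hits[hits$found, , drop = FALSE]
  qlen <- h$qend - h$qstart
  slen <- h$send - h$sstart
  gaps <- 2L * h$columns - qlen - slen  # each gap column consumes one base
  mism <- h$columns - gaps - h$matches
  ss <- ifelse(h$strand == "+", h$sstart + 1L, h$send)
  se <- ifelse(h$strand == "+", h$send, h$sstart + 1L)
  out <- data.frame(h$query, h$subject, sprintf("%.2f", h$identity),
                    h$columns, mism, gaps, h$qstart + 1L, h$qend,
                    ss, se, NA, h$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
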