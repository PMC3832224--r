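#' Recruit metagenomic reads against a genome
#'
#' Each read contributes at most one hit: its best local alignment against
#' the genome (both strands). A hit is kept iff it reaches `min_identity`
#' percent identity and an alignment length of `min_len` columns
#' (`mode = "abs_len"`, the classic "95% identity over at least 50 bp"
#' recruitment filter) or of at least `frac_len` of the read length
#' (`mode = "frac_len"`, the variant used for identity-vs-position island
#' plots). Per-position coverage is accumulated over kept hits and the
#' recruitment count is normalised by genome and database size:
#' `kept_hits / (genome_Mbp * database_Mbp)`, with database size the total
#' read bases / 1e6.
#'
#' @param reads a [read_set()].
#' @param genome an [annotated_genome()], or a prebuilt [build_index()] for
#'   repeated calls.
#' @param mode `"abs_len"` or `"frac_len"`.
#' @param min_identity percent identity cutoff.
#' @param min_len minimum alignment columns (`abs_len` mode).
#' @param frac_len minimum aligned fraction of the read (`frac_len` mode).
#' @param k seed length when `genome` is not already an index.
#' @param scoring see [best_local_hit()].
#' @return An object of class `recruitment_profile`: `genome`, `hits`
#'   (kept-hit `data.frame` as in [best_local_hit()]), `coverage` (integer
#'   vector over genome positions), `normalized` (hits per Mbp of genome per
#'   Mbp of database), `n_reads`, `n_kept`, `database_mbp`, `mode`.
#' @export
recruit <- function(reads, genome, mode = c("abs_len", "frac_len"),
                    min_identity = 95, min_len = 50L, frac_len = 0.5,
                    k = 13L, scoring = default_scoring()) {
  mode <- match.arg(mode)
  stopifnot(inherits(reads, "read_set"))
  if (!length(reads$ids)) stop("empty read set", call. = FALSE)
  if (inherits(genome, "seed_index")) {
    idx <- genome
  } else {
    stopifnot(inherits(genome, "annotated_genome"))
    idx <- build_index(genome, k = k)
  }
  glen <- idx$subject_length
  read_len <- nchar(reads$sequences)
  min_cols <- if (mode == "abs_len") as.integer(min_len)
              else as.integer(ceiling(frac_len * read_len))
  hits <- best_local_hit(reads$sequences, idx, min_identity = min_identity,
                         min_aln_len = min_cols, scoring = scoring,
                         query_id = reads$ids)
  kept <- hits[hits$found, , drop = FALSE]
  coverage <- interval_coverage(kept$sstart, kept$send, glen)
  db_mbp <- sum(read_len) / 1e6
  normalized <- nrow(kept) / ((glen / 1e6) * db_mbp)
  structure(list(genome = idx$subject_id, hits = kept, coverage = coverage,
                 normalized = normalized, n_reads = length(reads$ids),
                 n_kept = nrow(kept), genome_length = glen,
                 database_mbp = db_mbp, mode = mode,
                 params = list(min_identity = min_identity,
                               min_len = min_len, frac_len = frac_len, k = k)),
            class = "recruitment_profile")
}

## per-position coverage from 0-based half-open intervals (difference array)
interval_coverage <- function(starts, ends, n) {
  cov <- integer(n + 1L)
  if (length(starts)) {
    add <- tabulate(starts + 1L, nbins = n + 1L)
    sub <- tabulate(ends + 1L, nbins = n + 1L)
    cov <- cumsum(add - sub)
  } else cov <- integer(n)
  cov[seq_len(n)]
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("<recruitment_profile> %s: %d/%d reads kept (%s mode), %.3g hits/Mbp^2, mean coverage %.2f\n",
              x$genome, x$n_kept, x$n_reads, x$mode, x$normalized,
              mean(x$coverage)))
  invisible(x)
}

#' Recruit a read database against several genomes at once
#'
#' Each read is assigned to the genome where it aligns best; exact
#' score ties across genomes are counted fractionally (1/n to each), which
#' avoids abundance inflation when near-identical references compete for
#' the same reads. Per-genome profiles are built from each genome's
#' assigned reads.
#'
#' @inheritParams recruit
#' @param genomes list of [annotated_genome()] objects.
#' @return named list of `recruitment_profile`s with an extra
#'   `fractional_hits` field (kept hits with tie weights applied).
#' @export
recruit_community <- function(reads, genomes, mode = c("abs_len", "frac_len"),
                              min_identity = 95, min_len = 50L,
                              frac_len = 0.5, k = 13L,
                              scoring = default_scoring()) {
  mode <- match.arg(mode)
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  profiles <- lapply(genomes, function(g)
    recruit(reads, g, mode = mode, min_identity = min_identity,
            min_len = min_len, frac_len = frac_len, k = k, scoring = scoring))
  names(profiles) <- vapply(genomes, function(g) g$id, character(1))
  ## best genome per read by score; ties fractional
  score_tab <- matrix(NA_real_, nrow = length(reads$ids),
                      ncol = length(profiles),
                      dimnames = list(reads$ids, names(profiles)))
  for (j in seq_along(profiles)) {
    h <- profiles[[j]]$hits
    score_tab[match(h$query, reads$ids), j] <- h$score
  }
  best <- apply(score_tab, 1L, function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
  for (j in seq_along(profiles)) {
    is_best <- !is.na(score_tab[, j]) & score_tab[, j] == best
    n_tied <- rowSums(!is.na(score_tab) & score_tab == best, na.rm = TRUE)
    w <- ifelse(is_best, 1 / pmax(n_tied, 1L), 0)
    h <- profiles[[j]]$hits
    h$weight <- w[match(h$query, reads$ids)]
    h <- h[h$weight > 0, , drop = FALSE]
    profiles[[j]]$fractional_hits <- h
    glen <- profiles[[j]]$genome_length
    profiles[[j]]$normalized <- sum(h$weight) /
      ((glen / 1e6) * profiles[[j]]$database_mbp)
    profiles[[j]]$n_kept <- sum(h$weight)
    profiles[[j]]$coverage <- interval_coverage(h$sstart, h$send, glen)
  }
  profiles
}

#' Call genomic islands from a recruitment coverage profile
#'
#' Metagenomic islands are reference regions recruiting far fewer
#' near-identical reads than the genome-wide average, the footprint of gene
#' content that varies among co-occurring lineages. Sliding windows whose
#' mean coverage falls below `ratio_threshold` times the genome-wide median
#' windowed coverage are flagged; overlapping or near (within `merge_gap`)
#' flagged windows are merged and merged intervals shorter than `min_len`
#' are dropped. Calls are labelled GI1..GIn left to right.
#'
#' @param profile a [recruit()] result (or any object with `coverage` and
#'   `genome` fields).
#' @param window window size in nt.
#' @param step window step in nt.
#' @param ratio_threshold flag windows below this fraction of the median.
#' @param merge_gap merge flagged windows closer than this (nt).
#' @param min_len minimum island length (nt).
#' @return `data.frame` with `label`, `start`, `end` (0-based half-open),
#'   `mean_coverage`, `ratio` (island mean / genome median windowed
#'   coverage). Zero rows when coverage is uniform or degenerate (all-zero
#'   coverage or zero median raise a warning and return no calls).
#' @export
call_islands <- function(profile, window = 10000L, step = 1000L,
                         ratio_threshold = 0.2, merge_gap = 2000L,
                         min_len = 5000L) {
  cov <- profile$coverage
  n <- length(cov)
  empty <- data.frame(label = character(), start = integer(),
                      end = integer(), mean_coverage = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE)
  if (all(cov == 0)) {
    warnf("all-zero coverage on '%s': no island calls", profile$genome)
    return(empty)
  }
  if (n < window) {
    warnf("genome shorter than one window: no island calls")
    return(empty)
  }
  cs <- c(0, cumsum(as.numeric(cov)))
  starts <- seq.int(0L, n - window, by = step)
  wmean <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
  med <- median(wmean)
  if (med <= 0) {
    warnf("median windowed coverage is zero on '%s': no island calls",
          profile$genome)
    return(empty)
  }
  flagged <- wmean < ratio_threshold * med
  if (!any(flagged)) return(empty)
  ir <- IRanges::IRanges(start = starts[flagged] + 1L,
                         end = starts[flagged] + window)
  merged <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
  merged <- merged[IRanges::width(merged) >= min_len]
  if (!length(merged)) return(empty)
  s0 <- IRanges::start(merged) - 1L
  e0 <- IRanges::end(merged)
  mean_cov <- (cs[e0 + 1L] - cs[s0 + 1L]) / (e0 - s0)
  data.frame(label = paste0("GI", seq_along(s0)), start = s0, end = e0,
             mean_coverage = mean_cov, ratio = mean_cov / med,
             stringsAsFactors = FALSE)
}
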