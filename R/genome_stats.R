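#' GC content of a genome
#'
#' Fraction (G+C)/(A+C+G+T), case-insensitive. `N` bases are excluded from
#' the denominator.
#'
#' @param genome an [annotated_genome()] or a DNA string.
#' @return fraction in `[0, 1]`.
#' @examples
#' gc_content("GGCC")   # 1
#' gc_content("ATATAT") # 0
#' @export
gc_content <- function(genome) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence
         else toupper(as.character(genome))
  counts <- base_counts(seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence has no unambiguous bases", call. = FALSE)
  unname((counts["G"] + counts["C"]) / denom)
}

#' Intergenic spacer distribution
#'
#' Distances between consecutive features, the genome-streamlining signal:
#' dominant planktonic prokaryotes carry very short median spacers (14-19 nt
#' in the most streamlined halophile genomes) while larger free-living
#' genomes run far longer. Features of the selected kinds are sorted by
#' start, strand-blind; for each consecutive pair the spacer is
#' `start(next) - end(prev)`. Under `policy = "clamp"` (default) negative
#' gaps from overlapping genes count as 0, keeping one spacer per adjacent
#' pair; `policy = "exclude"` drops them.
#'
#' @param genome an [annotated_genome()].
#' @param kinds feature kinds to include (default protein-coding + RNA).
#' @param policy `"clamp"` or `"exclude"` for overlapping features.
#' @return An object of class `spacer_distribution`: list with `genome`,
#'   `spacers` (integer vector), `median`, `policy`.
#' @export
intergenic_spacers <- function(genome, kinds = c("CDS", "rRNA", "tRNA"),
                               policy = c("clamp", "exclude")) {
  stopifnot(inherits(genome, "annotated_genome"))
  policy <- match.arg(policy)
  f <- genome$features[genome$features$kind %in% kinds, , drop = FALSE]
  f <- f[order(f$start, f$end), , drop = FALSE]
  if (nrow(f) < 2L) {
    warnf("genome '%s': fewer than 2 features of the selected kinds; empty spacer distribution",
          genome$id)
    spacers <- integer()
  } else {
    spacers <- f$start[-1L] - f$end[-nrow(f)]
    if (policy == "clamp") spacers <- pmax(spacers, 0L)
    else spacers <- spacers[spacers >= 0L]
  }
  structure(list(genome = genome$id, spacers = as.integer(spacers),
                 median = if (length(spacers)) median(spacers) else NA_real_,
                 policy = policy),
            class = "spacer_distribution")
}

#' @export
print.spacer_distribution <- function(x, ...) {
  cat(sprintf("<spacer_distribution> %s: %d spacers, median %s nt (policy %s)\n",
              x$genome, length(x$spacers),
              format(x$median), x$policy))
  invisible(x)
}

#' Coding density
#'
#' Fraction of the genome covered by the union of CDS intervals; overlapping
#' or duplicated CDS are counted once.
#'
#' @param genome an [annotated_genome()].
#' @return fraction in `[0, 1]`.
#' @export
coding_density <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  f <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  if (!nrow(f)) stopf("genome '%s' has no CDS features", genome$id)
  ir <- IRanges::reduce(IRanges::IRanges(start = f$start + 1L, end = f$end))
  sum(IRanges::width(ir)) / genome$length
}

#' One-row streamlining summary of a genome
#'
#' @param genome an [annotated_genome()].
#' @param spacer_policy passed to [intergenic_spacers()].
#' @return `data.frame` with `genome`, `length`, `gc_percent`, `cds_count`,
#'   `coding_density`, `median_spacer`.
#' @export
genome_stats <- function(genome, spacer_policy = "clamp") {
  stopifnot(inherits(genome, "annotated_genome"))
  n_cds <- sum(genome$features$kind == "CDS")
  dens <- if (n_cds > 0) coding_density(genome) else NA_real_
  med <- suppressWarnings(intergenic_spacers(genome, policy = spacer_policy)$median)
  data.frame(genome = genome$id, length = genome$length,
             gc_percent = 100 * gc_content(genome),
             cds_count = n_cds, coding_density = dens,
             median_spacer = med, stringsAsFactors = FALSE)
}
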