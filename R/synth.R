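## Synthetic data with exact truth: genomes with planted gene/spacer
## layouts, diverged clonal lineages, flexible genomic islands carried by
## only part of the population, error-bearing fixed-length reads, and
## composition-controlled proteomes. Every generator is deterministic given
## its seed (Mersenne-Twister via `with_seed`); all stochastic structure is
## reconstructible from (spec, seed).

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Per-base G+C probability inside coding regions is tilted so that the
## realised GC (after excluding stop codons) matches the requested genome
## GC: rejection of AT-rich stop codons raises GC slightly, which matters
## at the +-0.01 tolerance the generator promises.
coding_gc_adjust <- function(gc) {
  realised <- function(p) {
    b <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
    p_stop <- b["T"] * b["A"] * b["A"] + b["T"] * b["A"] * b["G"] +
      b["T"] * b["G"] * b["A"]
    gc_stop <- (0 * b["T"] * b["A"] * b["A"] + 1 * b["T"] * b["A"] * b["G"] +
                  1 * b["T"] * b["G"] * b["A"]) / p_stop
    ## expected GC bases per codon conditional on non-stop, over 3 bases
    (3 * p - p_stop * gc_stop) / (3 * (1 - p_stop))
  }
  uniroot(function(p) realised(p) - gc, interval = c(1e-3, 1 - 1e-3),
          tol = 1e-9)$root
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## gene body: ATG + non-stop random codons + stop codon
random_gene <- function(len_nt, gc_coding) {
  n_codons <- max(2L, as.integer(round(len_nt / 3)))
  inner <- n_codons - 2L
  acc <- character(0)
  while (length(acc) < inner) {
    need <- inner - length(acc)
    b <- matrix(random_bases(3L * (need + need %/% 16L + 8L), gc_coding),
                nrow = 3L)
    cand <- paste0(b[1L, ], b[2L, ], b[3L, ])
    acc <- c(acc, cand[!cand %in% STOP_CODONS])
  }
  paste0("ATG", paste(acc[seq_len(inner)], collapse = ""),
         sample(STOP_CODONS, 1L, prob = c(0.6, 0.2, 0.2)))
}

#' Generate a synthetic annotated genome
#'
#' Alternating gene/spacer layout: gene lengths are drawn around
#' `mean_gene_len` (gamma, shape 4, rounded to codons), spacer lengths are
#' geometric with the stated mean, intergenic bases are i.i.d. at the
#' target GC and coding bases are i.i.d. codons (stop codons excluded
#' internally, GC-compensated). Genes alternate strand at random and carry
#' their translated proteins, so streamlining metrics, recruitment and pI
#' profiling all have exact planted truth.
#'
#' @param length genome length in nt.
#' @param gc target GC fraction in (0, 1).
#' @param mean_gene_len mean gene length in nt.
#' @param mean_spacer mean intergenic spacer in nt.
#' @param seed integer seed (mandatory; same seed, same genome).
#' @param id genome id.
#' @return An [annotated_genome()] with CDS features and proteins.
#' @export
generate_genome <- function(length, gc = 0.6, mean_gene_len = 1000L,
                            mean_spacer = 15L, seed, id = "synth") {
  if (gc <= 0 || gc >= 1) stop("`gc` must be in (0, 1)", call. = FALSE)
  if (mean_gene_len >= length)
    stop("`mean_gene_len` must be smaller than `length`", call. = FALSE)
  with_seed(seed, {
    gc_coding <- coding_gc_adjust(gc)
    parts <- character(0); feats <- list(); genes_nt <- character(0)
    pos <- 0L; i <- 0L
    while (pos < length) {
      i <- i + 1L
      spacer_len <- rgeom(1L, 1 / (mean_spacer + 1))
      gene_len <- 3L * max(30L, as.integer(round(rgamma(1L, shape = 4,
                                                        scale = mean_gene_len / 4) / 3)))
      if (pos + spacer_len + gene_len > length) {
        parts <- c(parts, paste(random_bases(length - pos, gc), collapse = ""))
        break
      }
      strand <- sample(c("+", "-"), 1L)
      gene <- random_gene(gene_len, gc_coding)
      placed <- if (strand == "-") dna_revcomp(gene) else gene
      parts <- c(parts,
                 if (spacer_len > 0) paste(random_bases(spacer_len, gc),
                                           collapse = "") else NULL,
                 placed)
      genes_nt <- c(genes_nt, gene)
      feats[[i]] <- data.frame(start = pos + spacer_len,
                               end = pos + spacer_len + nchar(gene),
                               strand = strand, kind = "CDS",
                               protein = NA_character_,
                               stringsAsFactors = FALSE)
      pos <- pos + spacer_len + nchar(gene)
    }
    feats <- feats[!vapply(feats, is.null, logical(1))]
    feats <- do.call(rbind, feats)
    ## translate all genes in one vectorized pass
    prots <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(genes_nt))))
    feats$protein <- sub("\\*$", "", prots)
    annotated_genome(id, paste(parts, collapse = ""), features = feats)
  })
}

#' Mutate a genome into a diverged clonal lineage
#'
#' Per-base i.i.d. substitutions at `rate`; each substituted base becomes
#' one of the three other bases uniformly. The returned log records every
#' change, so truth identity is exactly computable. No indels by default
#' (they would decouple the planted rate from alignment identity).
#'
#' @param genome an [annotated_genome()].
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @param id id of the derived lineage.
#' @return list with `genome` (the mutated [annotated_genome()], features
#'   carried over) and `log` (`data.frame` with 0-based `pos`, `ref`,
#'   `alt`).
#' @export
mutate_lineage <- function(genome, rate, seed, id = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  id <- id %||% paste0(genome$id, "_mut")
  with_seed(seed, {
    n <- genome$length
    n_mut <- rbinom(1L, n, rate)
    pos <- sort(sample.int(n, n_mut))
    bases <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    ref <- bases[pos]
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
      USE.NAMES = FALSE)
    bases[pos] <- alt
    mutated <- annotated_genome(id, paste(bases, collapse = ""),
                                features = genome$features,
                                topology = genome$topology)
    list(genome = mutated,
         log = data.frame(pos = pos - 1L, ref = ref, alt = alt,
                          stringsAsFactors = FALSE))
  })
}

#' Community specification for read simulation
#'
#' @param members list of member specs: each a list with `genome` (an
#'   [annotated_genome()]), `abundance` (> 0, relative), optional
#'   `divergence` (per-base lineage substitution rate, default 0) and
#'   optional `islands` (`data.frame` with `start`, `end` 0-based half-open
#'   and `frequency` in `[0, 1]`: the fraction of the population carrying
#'   that island).
#' @param read_length read length in nt.
#' @param n_reads number of reads.
#' @param error_rate per-base sequencing error (substitution) rate.
#' @param seed integer seed (mandatory).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(members, read_length = 100L, n_reads = 10000L,
                           error_rate = 0.005, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(is.list(members), length(members) >= 1L)
  for (m in members) {
    stopifnot(inherits(m$genome, "annotated_genome"))
    if (is.null(m$abundance) || m$abundance <= 0)
      stop("each member needs `abundance` > 0", call. = FALSE)
    if (!is.null(m$islands)) {
      stopifnot(all(c("start", "end", "frequency") %in% names(m$islands)))
      if (any(m$islands$frequency < 0 | m$islands$frequency > 1))
        stop("island frequencies must be in [0, 1]", call. = FALSE)
    }
  }
  structure(list(members = members, read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a truth-labelled metagenomic read set
#'
#' Reads are drawn from community members proportionally to
#' `abundance x genome length` (a cell's chance of yielding a read scales
#' with how much DNA it contributes), start positions uniform. If a member
#' declares a lineage `divergence`, reads are drawn from a mutated lineage
#' genome (one per member, derived deterministically from the community
#' seed). Flexible islands are sampled at their population `frequency`: for
#' every candidate read overlapping an island, a carrier/non-carrier cell is
#' drawn, and reads from non-carriers are re-placed elsewhere -- at
#' frequency 0 no read ever originates inside the island. Sequencing errors
#' are i.i.d. substitutions at `error_rate`. The truth table records source
#' member, source interval (reference coordinates) and island overlap.
#'
#' @param spec a [community_spec()].
#' @return A [read_set()] with a filled `truth` table.
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  rl <- spec$read_length
  glens <- vapply(spec$members, function(m) m$genome$length, numeric(1))
  if (rl > min(glens))
    stop("read length exceeds the shortest genome", call. = FALSE)
  with_seed(spec$seed, {
    ab <- vapply(spec$members, function(m) m$abundance, numeric(1))
    w <- ab * glens
    src <- sample.int(length(spec$members), spec$n_reads, replace = TRUE,
                      prob = w / sum(w))
    lineages <- lapply(seq_along(spec$members), function(i) {
      m <- spec$members[[i]]
      div <- m$divergence %||% 0
      if (div > 0)
        mutate_lineage(m$genome, div,
                       seed = (spec$seed + 7919L * i) %% .Machine$integer.max,
                       id = paste0(m$genome$id, "_lineage"))$genome$sequence
      else m$genome$sequence
    })
    ids <- sprintf("read%06d", seq_len(spec$n_reads))
    seqs <- character(spec$n_reads)
    starts <- integer(spec$n_reads)
    from_island <- logical(spec$n_reads)
    for (i in seq_along(spec$members)) {
      m <- spec$members[[i]]
      sel <- which(src == i)
      if (!length(sel)) next
      n_i <- length(sel)
      glen <- glens[i]
      st <- sample.int(glen - rl + 1L, n_i, replace = TRUE) - 1L
      isl <- m$islands
      if (!is.null(isl) && nrow(isl)) {
        ## re-place reads drawn from cells that lack the island they
        ## overlap; carrier status is drawn once per placement attempt
        unsettled <- rep(TRUE, n_i)
        while (any(unsettled)) {
          act <- which(unsettled)
          redraw <- rep(FALSE, length(act))
          for (r in seq_len(nrow(isl))) {
            ov <- st[act] < isl$end[r] & (st[act] + rl) > isl$start[r]
            carrier <- runif(length(act)) < isl$frequency[r]
            redraw <- redraw | (ov & !carrier)
          }
          unsettled[act] <- FALSE
          if (any(redraw)) {
            st[act[redraw]] <- sample.int(glen - rl + 1L, sum(redraw),
                                          replace = TRUE) - 1L
            unsettled[act[redraw]] <- TRUE
          }
        }
        overlap_any <- rep(FALSE, n_i)
        for (r in seq_len(nrow(isl))) {
          ov <- st < isl$end[r] & (st + rl) > isl$start[r]
          overlap_any <- overlap_any | ov
        }
        from_island[sel] <- overlap_any
      }
      starts[sel] <- st
      seqs[sel] <- substring(lineages[[i]], st + 1L, st + rl)
    }
    ## strand: half the reads come from the reverse strand
    rev_sel <- runif(spec$n_reads) < 0.5
    if (any(rev_sel)) {
      x <- Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev_sel]))
      seqs[rev_sel] <- as.character(x)
    }
    ## sequencing errors
    if (spec$error_rate > 0) {
      n_err <- rbinom(spec$n_reads, rl, spec$error_rate)
      which_err <- which(n_err > 0)
      for (j in which_err) {
        p <- sample.int(rl, n_err[j])
        s <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
        s[p] <- vapply(s[p], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
          USE.NAMES = FALSE)
        seqs[j] <- paste(s, collapse = "")
      }
    }
    truth <- data.frame(read = ids,
                        genome = vapply(spec$members,
                                        function(m) m$genome$id,
                                        character(1))[src],
                        start = starts, end = starts + rl,
                        strand = ifelse(rev_sel, "-", "+"),
                        from_island = from_island,
                        stringsAsFactors = FALSE)
    read_set(ids, seqs, truth = truth)
  })
}

## average amino-acid composition of a typical bacterial proteome, and the
## charged-residue tilts applied per protein class
aa_background <- function() {
  c(A = 0.089, R = 0.055, N = 0.039, D = 0.054, C = 0.011, Q = 0.038,
    E = 0.062, G = 0.074, H = 0.023, I = 0.056, L = 0.100, K = 0.044,
    M = 0.024, F = 0.039, P = 0.044, S = 0.055, T = 0.053, W = 0.013,
    Y = 0.029, V = 0.069)
}

tilt_composition <- function(d, e, k, r) {
  comp <- aa_background()
  comp[c("D", "E", "K", "R")] <- c(d, e, k, r)
  comp / sum(comp)
}

#' Generate a style-controlled synthetic proteome
#'
#' Proteomes are modelled as a mixture of an acid-leaning cytoplasmic class
#' and a base-leaning (membrane/ribosomal) class -- the two modes of the
#' classical bimodal "virtual 2D-gel". `"freshwater"` draws 60% of proteins
#' from the acidic class and 40% from the basic class, giving the bimodal
#' acidic + basic profile of non-halophiles. `"halophile"` draws every
#' protein from a strongly acidified composition (combined D+E >= 15%,
#' basic residues depleted), collapsing the basic mode into the single
#' acidic peak typical of salt-exposed proteomes. Protein lengths are
#' gamma-distributed (mean 300, minimum 50 residues).
#'
#' @param style `"halophile"` or `"freshwater"`.
#' @param n_proteins number of proteins.
#' @param seed integer seed.
#' @return character vector of proteins; attribute `"composition"` records
#'   the class compositions and mixture weights, attribute `"class"` the
#'   per-protein class labels.
#' @export
generate_proteome <- function(style = c("halophile", "freshwater"),
                              n_proteins = 500L, seed) {
  style <- match.arg(style)
  acid <- tilt_composition(d = 0.075, e = 0.085, k = 0.033, r = 0.038)
  base <- tilt_composition(d = 0.032, e = 0.038, k = 0.080, r = 0.085)
  halo <- tilt_composition(d = 0.090, e = 0.095, k = 0.024, r = 0.026)
  if (style == "halophile") {
    classes <- list(halo = halo); weights <- 1
  } else {
    classes <- list(acid = acid, base = base); weights <- c(0.6, 0.4)
  }
  with_seed(seed, {
    lens <- pmax(50L, as.integer(round(rgamma(n_proteins, shape = 3,
                                              scale = 100))))
    cls <- sample(names(classes), n_proteins, replace = TRUE, prob = weights)
    out <- vapply(seq_len(n_proteins), function(i) {
      comp <- classes[[cls[i]]]
      paste(sample(names(comp), lens[i], replace = TRUE, prob = comp),
            collapse = "")
    }, character(1))
    attr(out, "composition") <- list(classes = classes, weights = weights)
    attr(out, "class") <- cls
    out
  })
}
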