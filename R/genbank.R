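## GenBank flat-file reader.
##
## Covers the subset of the format needed for complete prokaryotic
## replicons: LOCUS line (length, topology), the FEATURES table with
## single-interval, complement() and join() locations, the /translation
## qualifier, and the ORIGIN sequence block. Locations are converted from
## 1-based inclusive to 0-based half-open on ingest. join() locations are
## collapsed to their spanning interval; joins that wrap the origin of a
## circular replicon are skipped with a warning (the replicon is linearized
## at position 0 and origin-spanning features are not reconstructed).

#' Read a GenBank flat file
#'
#' @param path GenBank flat-file path.
#' @param id override the LOCUS name.
#' @return An [annotated_genome()]. CDS proteins come from the
#'   `/translation` qualifier when present, otherwise they are translated
#'   from the sequence with the standard code (trailing stop removed).
#' @export
read_genbank <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stopf("'%s' line 1: not a GenBank flat file (missing LOCUS)", path)
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_id <- id %||% locus[2]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at))
    stopf("'%s': no ORIGIN sequence block", path)
  origin_at <- origin_at[1]
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_at + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- gsub("[^ACGTN]", "N", sequence)

  feat_at <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_at)) {
    block <- lines[seq(feat_at[1] + 1L, origin_at - 1L)]
    features <- parse_gb_features(block, sequence, path)
  }
  annotated_genome(rec_id, sequence, features = features, topology = topology)
}

parse_gb_features <- function(block, sequence, path) {
  ## feature headers start at column 6 (5 spaces + key); qualifier and
  ## continuation lines are indented to column 22
  is_header <- grepl("^ {5}\\S", block)
  idx <- which(is_header)
  if (!length(idx)) return(empty_features())
  out <- vector("list", length(idx))
  bounds <- c(idx, length(block) + 1L)
  n <- nchar(sequence)
  for (i in seq_along(idx)) {
    lns <- block[seq(bounds[i], bounds[i + 1L] - 1L)]
    key <- sub("^ {5}(\\S+).*$", "\\1", lns[1])
    if (key %in% c("source")) next
    ## location may continue over lines until the first qualifier (/...)
    qual_start <- grep("^ +/", lns)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(lns)
    loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", lns[1]),
                          if (loc_end >= 2) trimws(lns[2:loc_end]))),
                 collapse = "")
    parsed <- parse_gb_location(loc)
    if (is.null(parsed)) {
      warnf("skipping feature with unsupported location '%s'", loc)
      next
    }
    if (parsed$wraps) {
      warnf("skipping origin-spanning feature '%s' (%s)", key, loc)
      next
    }
    kind <- if (key %in% c("CDS", "rRNA", "tRNA")) key else "other"
    if (key == "gene") next  # gene duplicates its CDS/RNA child interval
    protein <- NA_character_
    if (kind == "CDS") {
      protein <- extract_gb_translation(lns)
      if (is.na(protein)) {
        if (parsed$end > n)
          stopf("'%s': CDS %s extends beyond sequence end (%d)", path, loc, n)
        nt <- substr(sequence, parsed$start + 1L, parsed$end)
        if (parsed$strand == "-") nt <- dna_revcomp(nt)
        protein <- translate_cds(nt)
      }
    }
    if (parsed$end > n)
      stopf("'%s': feature %s outside sequence [0, %d)", path, loc, n)
    out[[i]] <- data.frame(start = parsed$start, end = parsed$end,
                           strand = parsed$strand, kind = kind,
                           protein = protein, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_features())
  do.call(rbind, out)
}

## "123..456", "complement(123..456)", "join(1..5,10..20)",
## "complement(join(...))"; <,> partial markers tolerated.
parse_gb_location <- function(loc) {
  strand <- "+"
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x) || grepl("^order\\(", x))
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  x <- gsub("[<>]", "", x)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  starts <- ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^\\d+$", p)) { starts[i] <- ends[i] <- as.integer(p) }
    else if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      starts[i] <- se[1]; ends[i] <- se[2]
    } else return(NULL)
  }
  wraps <- any(starts > ends)
  list(start = min(starts) - 1L, end = max(ends), strand = strand,
       wraps = wraps)
}

extract_gb_translation <- function(lns) {
  at <- grep("^ +/translation=\"", lns)
  if (!length(at)) return(NA_character_)
  i <- at[1]
  piece <- sub("^ +/translation=\"", "", lns[i])
  acc <- character()
  repeat {
    closed <- grepl("\"", piece)
    acc <- c(acc, gsub("\"", "", piece))
    if (closed || i >= length(lns)) break
    i <- i + 1L
    piece <- trimws(lns[i])
  }
  paste(acc, collapse = "")
}
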