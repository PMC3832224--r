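#' pKa tables for isoelectric-point calculation
#'
#' Per-group dissociation constants used by [isoelectric_point()]. The
#' default is the EMBOSS `iep` set; `"sillero"` is provided as an
#' alternative. Groups: `Nterm`, `K`, `R`, `H` (basic); `Cterm`, `D`, `E`,
#' `C`, `Y` (acidic).
#'
#' @param name `"emboss"` or `"sillero"`.
#' @return named numeric vector of pKa values.
#' @export
pka_set <- function(name = c("emboss", "sillero")) {
  name <- match.arg(name)
  switch(name,
    emboss = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5,
               Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    sillero = c(Nterm = 8.2, K = 10.4, R = 12.0, H = 6.4,
                Cterm = 3.2, D = 4.0, E = 4.5, C = 9.0, Y = 10.0))
}

BASIC_GROUPS <- c("Nterm", "K", "R", "H")
ACIDIC_GROUPS <- c("Cterm", "D", "E", "C", "Y")

## counts matrix (proteins x groups); termini count once per protein.
## Unknown residues (X, B, Z, ...) carry no charge.
ionizable_counts <- function(proteins) {
  aa <- c("K", "R", "H", "D", "E", "C", "Y")
  m <- matrix(0, nrow = length(proteins), ncol = length(aa),
              dimnames = list(NULL, aa))
  up <- toupper(proteins)
  for (a in aa)
    m[, a] <- nchar(up) - nchar(gsub(a, "", up, fixed = TRUE))
  cbind(Nterm = 1, Cterm = 1, m)
}

## Net charge of each protein (rows of `counts`) at its pH; `pH` is a
## scalar or one value per protein.
net_charge <- function(counts, pH, pka) {
  pow_pH <- 10^pH
  charge <- numeric(nrow(counts))
  for (g in BASIC_GROUPS)
    charge <- charge + counts[, g] * 10^pka[[g]] / (pow_pH + 10^pka[[g]])
  for (g in ACIDIC_GROUPS)
    charge <- charge - counts[, g] * pow_pH / (pow_pH + 10^pka[[g]])
  charge
}

#' Protein isoelectric point
#'
#' The pH at which the net charge is zero under a per-group
#' Henderson-Hasselbalch model: basic groups (N-terminus, K, R, H)
#' contribute `10^pKa / (10^pH + 10^pKa)`, acidic groups (C-terminus, D, E,
#' C, Y) contribute `-10^pH / (10^pH + 10^pKa)`. Solved by bisection on
#' `[0, 14]` until `|charge| < 1e-4` or the interval is narrower than
#' `1e-4`. Unknown residues (X, B, Z) carry no charge.
#'
#' @param protein amino-acid string(s); vectorized.
#' @param pka named pKa vector, see [pka_set()].
#' @return numeric vector of pI values in `[0, 14]`.
#' @examples
#' isoelectric_point("A")  # (8.6 + 3.6) / 2 = 6.1 with the EMBOSS set
#' @export
isoelectric_point <- function(protein, pka = pka_set("emboss")) {
  protein <- as.character(protein)
  if (!length(protein)) return(numeric())
  if (any(!nzchar(protein))) stop("empty protein sequence", call. = FALSE)
  counts <- ionizable_counts(protein)
  lo <- rep(0, length(protein)); hi <- rep(14, length(protein))
  repeat {
    mid <- (lo + hi) / 2
    ch <- net_charge(counts, mid, pka)
    done <- abs(ch) < 1e-4 | (hi - lo) < 1e-4
    pos <- ch > 0 & !done
    lo[pos] <- mid[pos]
    neg <- ch <= 0 & !done
    hi[neg] <- mid[neg]
    if (all(done)) return(mid)
  }
}

#' Whole-proteome isoelectric-point profile ("virtual 2D-gel")
#'
#' Computes one pI per protein, a binned density over a fixed pH grid and
#' the peaks of the kernel-smoothed density. Salt-in halophile proteomes
#' show a single strongly acidic peak (around pI 5) where non-halophiles
#' show the classical bimodal acidic + basic shape, so the peak structure is
#' the diagnostic output. Proteins shorter than `min_len` or containing
#' internal stops (`*`) are excluded and reported in the QC counts.
#'
#' @param genome an [annotated_genome()] with CDS proteins, or a character
#'   vector of protein sequences.
#' @param id profile label when `genome` is a character vector.
#' @param pka pKa table, see [pka_set()].
#' @param bin_width histogram bin width in pH units.
#' @param bandwidth Gaussian smoothing bandwidth (pH units) for peak calling.
#' @param min_peak_frac local maxima below this fraction of the highest
#'   smoothed density are not reported as peaks.
#' @param min_len minimum protein length scored.
#' @return An object of class `pi_profile`: `genome`, `pi` (per protein),
#'   `density` (`data.frame` grid/count), `peaks` (pH of local maxima),
#'   `qc` (scored / excluded counts).
#' @export
proteome_profile <- function(genome, id = NULL, pka = pka_set("emboss"),
                             bin_width = 0.2, bandwidth = 0.3,
                             min_peak_frac = 0.1, min_len = 10L) {
  if (inherits(genome, "annotated_genome")) {
    proteins <- genome$features$protein[genome$features$kind == "CDS"]
    proteins <- proteins[!is.na(proteins)]
    id <- id %||% genome$id
  } else {
    proteins <- as.character(genome)
    id <- id %||% "proteome"
  }
  if (!length(proteins)) stop("no CDS proteins to profile", call. = FALSE)
  ok <- nchar(proteins) >= min_len & !grepl("*", proteins, fixed = TRUE)
  qc <- c(scored = sum(ok), excluded = sum(!ok))
  if (!any(ok)) stop("all proteins excluded by QC", call. = FALSE)
  pi_values <- isoelectric_point(proteins[ok], pka = pka)
  breaks <- seq(0, 14 + bin_width, by = bin_width)
  breaks <- breaks[breaks <= 14 + 1e-9]
  if (breaks[length(breaks)] < 14) breaks <- c(breaks, 14)
  counts <- as.integer(table(cut(pi_values, breaks = breaks,
                                 include.lowest = TRUE, right = FALSE)))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  smoothed <- smooth_density(centers, counts, bandwidth)
  peaks <- centers[find_peaks(smoothed, min_peak_frac)]
  structure(list(genome = id, pi = pi_values,
                 density = data.frame(grid = centers, count = counts,
                                      smoothed = smoothed),
                 peaks = peaks, qc = qc,
                 params = list(bin_width = bin_width, bandwidth = bandwidth,
                               min_peak_frac = min_peak_frac)),
            class = "pi_profile")
}

## discrete Gaussian kernel smoothing of binned counts on the pH grid
smooth_density <- function(centers, counts, bandwidth) {
  vapply(centers, function(x) {
    w <- exp(-0.5 * ((centers - x) / bandwidth)^2)
    sum(w * counts) / sum(w)
  }, numeric(1))
}

## Local maxima filtered by height and by topographic prominence (height
## above the deepest col separating the peak from any higher ground), both
## relative to the global maximum: shoulders and ripples on the flank of a
## mode are not separate peaks.
find_peaks <- function(y, min_frac, min_prominence = min_frac) {
  n <- length(y)
  if (n < 3 || max(y) <= 0) return(integer())
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  ## the pH scale is truncated at [0, 14]: a mode pressed against either
  ## boundary shows up as a monotone run into the edge bin
  if (y[1] > y[2]) idx <- c(1L, idx)
  if (y[n] > y[n - 1]) idx <- c(idx, n)
  idx <- idx[y[idx] >= min_frac * max(y)]
  keep <- vapply(idx, function(i) {
    higher <- which(y > y[i])
    if (!length(higher)) return(TRUE) # global maximum
    left <- higher[higher < i]; right <- higher[higher > i]
    cols <- c(if (length(left)) min(y[max(left):i]),
              if (length(right)) min(y[i:min(right)]))
    (y[i] - max(cols)) >= min_prominence * max(y)
  }, logical(1))
  idx[keep]
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("<pi_profile> %s: %d proteins (median pI %.2f), peaks at %s\n",
              x$genome, length(x$pi), median(x$pi),
              paste(sprintf("%.1f", x$peaks), collapse = ", ")))
  invisible(x)
}

#' Acidity summary of a pI profile
#'
#' @param profile a [proteome_profile()] result.
#' @return list with `acidic_fraction` (share of proteins with pI < 7) and
#'   `median_pi`.
#' @export
acidity_summary <- function(profile) {
  stopifnot(inherits(profile, "pi_profile"))
  if (!length(profile$pi)) stop("empty pI profile", call. = FALSE)
  list(acidic_fraction = mean(profile$pi < 7), median_pi = median(profile$pi))
}
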