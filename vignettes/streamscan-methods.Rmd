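---
title: "Methods: streamlining metrics, recruitment and proteome acidity"
author: "streamscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streamlining metrics, recruitment and proteome acidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`streamscan` implements the comparative-genomics computations used to
characterise streamlined, ecologically dominant halophilic prokaryotes:

* **streamlining metrics** — GC content, coding density and the
  intergenic-spacer distribution, whose median (14–19 nt in the most
  streamlined halophile genomes, versus hundreds of nt in larger
  free-living relatives) is the classic footprint of genome reduction;
* **fragment-based ANI** between genome pairs;
* **metagenomic fragment recruitment** of a read database against a
  reference genome, with size-normalised abundance and identity filters;
* **genomic-island calling** from the recruitment coverage profile;
* **whole-proteome isoelectric-point ("virtual 2D-gel") profiles**, the
  acidity signature that separates salt-exposed proteomes from the
  classical bimodal shape of non-halophiles;
* a **synthetic community generator** that plants all of the above with
  exact truth, so every analysis is testable end to end.

All internal coordinates are 0-based half-open; GenBank and GFF3 input
(1-based inclusive) is converted at the boundary, which removes the usual
off-by-one error class. Circular replicons are linearized at position 0;
features or alignments spanning the origin are not reconstructed (a
deliberate simplification — complete prokaryotic replicons are conventionally
analysed linearized from a fixed origin, and at most one feature per genome
is affected).

# Alignment engine

Both recruitment and ANI share one local aligner (C++): exact *k*-mer seeds
over the subject, seeds grouped per diagonal band, and a banded affine-gap
Smith–Waterman extension around each band on both strands. Scoring is fixed
at match +1, mismatch −2, gap open −5, gap extend −2 (a gap of length
*L* costs 5 + 2*L*); percent identity counts gap columns in the
denominator, matching the identity BLAST reports. Columns containing `N`
never match. Only the best hit per query is kept — recruitment counts each
read once — with ties broken toward the lower subject start, then the
forward strand.

Defaults: `k = 13` for read recruitment (sensitivity at the ≥95% identity
regime), `k = 11` for ANI fragments (sensitive down to the 70–80% identity
range: at 20% divergence an intact 11-mer occurs every ~12 bp in
expectation). Diagonal clusters far poorer in seeds than the densest
cluster cannot carry the best alignment in these regimes and are skipped; on
small subjects (≲ 400 kb of DP cells) the aligner falls back to an
exhaustive DP over the whole subject, so the seeded path and the exact path
coincide whenever any seed exists. The test suite verifies ≥99% score
agreement against an independent exhaustive Smith–Waterman
(`Biostrings::pairwiseAlignment`) on 60-bp pairs spanning unrelated and
5–20%-diverged sequences; disagreement is confined to the documented miss
class (no seed of length *k* exists).

# ANI

The query genome is cut into consecutive non-overlapping 1020-nt fragments
(terminal remainder discarded); each fragment's best local hit against the
subject is retained iff it reaches ≥30% identity over ≥70% of the fragment
length, and ANI is the mean identity of retained fragments — the
conventional fragment-based (BLAST-style) ANI recipe. Because the
literature reports a single number without stating a direction, the
headline value is the direction whose query id sorts first alphabetically,
and both directions plus their mean are always reported. All three
thresholds and the fragment length are configuration keys.

Local alignment trims a few terminal mismatches, which biases identity
upward very slightly; measured on planted lineages the bias is < 0.1 points
at ≤10% divergence and ~0.3 points at 20%, which is why the recovery tests
hold ANI to ±0.5 of (100 − rate) in the 1–10% range but only require
monotonicity through 20%.

# Recruitment and islands

Reads are aligned individually; a read is recruited iff its best hit
reaches ≥95% identity over ≥50 alignment columns (`abs_len`, the classical
recruitment-plot filter) or over ≥50% of the read length (`frac_len`, the
variant used for identity-vs-position island plots). The normalised
recruitment value is `kept_hits / (genome_Mbp × database_Mbp)` with the
database size equal to total read bases; the literature states only
"normalised against genome and database sizes", so this symmetric per-Mbp²
form is declared explicitly and unit-tested (appending non-recruiting reads
that double the database exactly halves the value). In multi-genome
comparisons each read is assigned to its best-scoring genome; exact score
ties are counted fractionally (1/n to each) to avoid abundance inflation
between near-identical references.

Islands are called from per-position coverage: sliding windows (10 kb
window, 1 kb step) whose mean coverage falls below 0.2× the genome-wide
median windowed coverage are flagged, overlapping or near (≤2 kb) windows
merged, merged intervals <5 kb dropped, labels GI1..GIn assigned left to
right. The published material shows plotted islands but no algorithm, so
these window parameters are package defaults, all exposed in the
configuration. By construction a sharp zero-coverage island of length *L*
is called as an interval within ±2 kb of its true edges, hence ≥80%
reciprocal overlap requires *L* ≳ 20 kb; the recovery criterion (≥2 of 3
planted islands of 15/25/40 kb) reflects exactly this resolution limit.
Degenerate profiles (all-zero coverage, zero median) produce a warning and
an empty call set rather than islands everywhere.

# Isoelectric points

Net charge is the sum of Henderson–Hasselbalch terms over basic groups
(N-terminus, K, R, H) and acidic groups (C-terminus, D, E, C, Y); the pI is
found by bisection on [0, 14] to |charge| < 1e-4 or interval < 1e-4.
The default pKa table is the EMBOSS `iep` set (N-term 8.6, K 10.8, R 12.5,
H 6.5, C-term 3.6, D 3.9, E 4.1, C 8.5, Y 10.1); no specific table is
canonical in the literature and the Sillero set is provided as an
alternative. Absolute pI values shift by a few tenths between tables, so
cross-proteome comparisons should fix one table; profile *shapes* (single
acidic peak vs bimodal) are robust to the choice. Unknown residues (X, B,
Z) carry no charge. Proteins shorter than 10 aa or containing internal
stops are excluded and counted in a QC report, since pseudogene fragments
distort the density tail.

Profiles are binned at 0.2 pH and smoothed with a fixed 0.3-pH Gaussian
kernel (the published figures state neither; these are declared defaults,
not inferred ones). Peaks are local maxima of the smoothed density filtered
by height and topographic prominence (both ≥10% of the global maximum), so
shoulders and ripples on a mode's flank are not separate peaks; a mode
pressed against either end of the truncated pH scale is detected via the
edge bins.

# Synthetic data: what it emulates, and what it does not

The generator is the package's ground truth and defines the study
conditions; its defaults are not tuned per analysis.

* **Genomes** — i.i.d. bases at a target GC with an alternating
  gene/spacer layout: gamma gene lengths (mean 1000 nt), geometric spacer
  lengths (mean 15 nt, matching the streamlined regime), genes on random
  strands built from non-stop codons (with the codon base distribution
  solved numerically so that realised GC matches the target after stop
  exclusion) and carrying their translations.
* **Lineages** — i.i.d. substitutions at a stated rate with a complete
  mutation log; no indels by default, so planted rate and alignment
  identity remain exactly comparable (indel mode would exercise the
  aligner, not the truth accounting).
* **Communities** — reads drawn proportionally to abundance × genome
  length, uniform starts, half on the reverse strand, i.i.d. substitution
  errors at 0.5% (a realistic short-read scale); flexible islands carry a
  population frequency, and a read overlapping an island is kept only if
  its (per-read) carrier draw succeeds, otherwise it is re-placed — at
  frequency 0 no read ever originates in the island, the limiting case
  behind metagenomic island dips.
* **Proteomes** — a mixture of an acid-leaning and a base-leaning residue
  composition around a typical bacterial background. The non-halophile
  ("freshwater") style draws 60/40 from the two classes, reproducing the
  classical bimodal virtual-2D-gel; the halophile style draws everything
  from a strongly acidified composition (D+E ≥ 15%, K/R depleted),
  collapsing the basic mode into a single acidic peak. The two-class
  mixture is deliberate: the bimodality of real proteomes comes from a
  distinct basic (membrane/ribosomal) subpopulation, and a single
  unstructured composition does not produce it robustly.

What the generator does **not** emulate: platform-specific error profiles,
indels, repeats and mobile elements, codon usage and amino-acid composition
structure beyond the charged residues, GC skew, and origin-spanning
features. Passing the recovery tests therefore demonstrates correctness of
the computations under the stated statistical model, not performance on
real sequencing artefacts.

Determinism: every stochastic entry point takes a mandatory integer seed
and runs under a locally scoped Mersenne-Twister state, so each synthetic
dataset is reconstructible from its (spec, seed) pair, byte for byte,
independent of call order.

# Numerical and design choices

* Spacers are gaps between consecutive features sorted by start,
  strand-blind (the published comparison states no strand rule); negative
  gaps from overlapping genes are clamped to 0 by default, which keeps one
  spacer per adjacent pair and biases the median downward consistently; an
  `exclude` policy is available.
* Coding density is the union of CDS intervals over genome length;
  duplicated or overlapping CDS count once.
* GC excludes `N` from the denominator; an all-`N` sequence is an error,
  not a 0.
* ANI of a genome with itself is exactly 100; a pair with zero retained
  fragments is flagged `undefined` rather than returning NaN.
* Problem sizes in the tests and the acceptance script (300-kb genomes for
  ANI recovery, 500 kb / 50k reads for island recovery, 1000 pairs for the
  aligner oracle, 500 proteins for the pI oracle) were chosen to give the
  recovery statistics tight sampling error while keeping a full run in the
  low minutes on a single CPU; all scale linearly if larger runs are
  wanted.

# Known limitations

* The aligner retains a single best hit per query: multi-HSP chaining
  across distant loci, E-values and protein alignment are out of scope.
* Island resolution is bounded below by the window size (islands ≲ 10 kb
  are invisible, 10–20 kb are found but with <80% reciprocal overlap).
* GenBank parsing covers complete single-record prokaryotic replicons
  (LOCUS/FEATURES/ORIGIN, `join`/`complement` locations, multi-line
  `/translation`); rich multi-record or contig-set files are out of scope.
* Recruitment reports plot-ready tables (hits, coverage, islands), not
  rendered figures.
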