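# streamscan

Comparative genomics and metagenomic recruitment for streamlined
halophilic prokaryotes — the computations used to establish that a
genome-reduced, planktonic moderate halophile dominates intermediate-salinity
(10–25%) hypersaline waters.

Dominant planktonic microbes tend to carry *streamlined* genomes: small
replicons, coding densities above 90%, median intergenic spacers of only
14–19 nt, few regulatory systems and mobile elements. Their in-situ
abundance is read off metagenomes by *fragment recruitment* — aligning
environmental reads against a reference genome and counting hits that pass a
strict identity filter — and the recruitment coverage profile reveals
*metagenomic islands*, regions where co-occurring lineages diverge.
Salt-exposed proteomes leave an additional signature: the whole-proteome
isoelectric-point distribution collapses from the usual bimodal shape into a
single acidic peak. `streamscan` implements all of these, plus the
fragment-based average nucleotide identity (ANI) used to delimit species,
and a deterministic synthetic-community generator so that every computation
can be verified against planted truth.

## Core definitions

* **GC content** = (G+C)/(A+C+G+T), `N` excluded.
* **Coding density** = |union of CDS intervals| / genome length.
* **Intergenic spacer** = `max(0, start(next) − end(prev))` over consecutive
  features sorted by start, strand-blind.
* **ANI** = mean percent identity of 1020-nt genome fragments whose best
  local alignment reaches ≥30% identity over ≥70% of the fragment;
  ~95% corresponds to the species boundary.
* **Recruitment** keeps each read's single best hit iff identity ≥ 95% over
  ≥ 50 bp (or ≥ 50% of the read length, for island plots); the normalised
  value is `hits / (genome_Mbp × database_Mbp)`.
* **Islands** = merged sliding windows whose mean coverage falls below 0.2×
  the genome-wide median windowed coverage.
* **pI** = pH at which the Henderson–Hasselbalch net charge over ionizable
  groups is zero, solved by bisection (EMBOSS pKa set by default).

Alignment (shared by recruitment and ANI) is a self-contained seed-and-extend
banded Smith–Waterman (match +1, mismatch −2, gap open −5, extend −2),
validated in the test suite against an independent exhaustive
Smith–Waterman oracle.

## Worked example

```r
library(streamscan)

# a synthetic streamlined genome and a 5%-diverged clonal lineage
g1 <- generate_genome(60000, gc = 0.62, mean_gene_len = 900,
                      mean_spacer = 15, seed = 101, id = "sim1")
g2 <- mutate_lineage(g1, 0.05, seed = 55, id = "sim1_lineage")$genome

genome_stats(g1)
#>  genome length gc_percent cds_count coding_density median_spacer
#>    sim1  60000   61.70833        62        0.96685             8

ani(g1, g2)
#> <ani_result> sim1 vs sim1_lineage: ANI 95.0% (q->s 95.0, s->q 95.0,
#>   mean 95.0); 58/58 fragments retained
```

The genome comes back with the planted streamlining signature (96.7% coding,
8-nt median spacer, GC near target), and ANI recovers the planted 5%
divergence as 95.0%.

```r
# a community in which a 15-kb island is absent from every sequenced cell
rs <- simulate_reads(community_spec(
  list(list(genome = g1, abundance = 1,
            islands = data.frame(start = 20000, end = 35000, frequency = 0))),
  n_reads = 20000, seed = 7))

prof <- recruit(rs, g1)          # 95% identity / 50 bp filter
#> <recruitment_profile> sim1: 20000/20000 reads kept (abs_len mode),
#>   1.67e+05 hits/Mbp^2, mean coverage 33.31

call_islands(prof)
#>  label start   end mean_coverage     ratio
#>    GI1 18000 37000      9.061526 0.2078618
```

The single zero-frequency island is recovered within 2 kb of its planted
coordinates (window-size resolution), with the depressed coverage ratio
reported against the genome-wide median.

```r
prot <- generate_proteome("halophile", 500, seed = 3)
proteome_profile(prot, id = "halophile")
#> <pi_profile> halophile: 500 proteins (median pI 3.83), peaks at 3.9
```

A salt-adapted proteome shows the single acidic peak; the `"freshwater"`
style produces the classical bimodal profile.

The whole pipeline also runs from one YAML configuration
(`run_pipeline(system.file("extdata/demo_config.yaml", package = "streamscan"),
out_dir = "demo_out")`), and a thin CLI lives at
`inst/scripts/streamline-scan` with subcommands `stats`, `pi`, `ani`,
`recruit`, `simulate`, `run`.

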