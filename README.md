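# srnaplace

Local-context placement of multi-mapping small RNA-seq reads, with a
ground-truth read simulator and a benchmarking suite.

## The problem

In plant small RNA-seq, a large fraction of 21–24-nt reads align equally
well to several genomic positions (multi-mapping, "MMAP" reads; the number
of equally best positions is the read's MMAP-value *n*). Random placement
mis-places most of them; discarding them loses much of the library exactly
in the repeat-rich regions where heterochromatic siRNAs act. `srnaplace`
selects one primary alignment per read using the *local context* of each
candidate position: small RNA production is locus-concentrated, so the true
origin usually has other — often uniquely aligned — reads nearby, while the
silent copies of a repeat do not.

## The method

All exact-match positions of every read are enumerated (both strands, up to
a cap of 50 per read). The genome is divided into 50-nt bins; every
alignment belongs to the bin of its leftmost nucleotide, and the *vicinity*
of a candidate site is the five-bin (~250-nt) window centered on its bin.
One pass over the all-alignment map tallies, per bin, `u` (alignments of
uniquely aligned reads) and `f` (each site of a read with MMAP-value *n*
contributes 1/*n*). For a read with candidate sites *i* = 1…*n*:

| mode | probability of site *i* |
|------|--------------------------|
| R (random) | 1/*n* |
| U (unique-weighting) | u_i / Σ_j u_j over the vicinities |
| F (fractional) | f_i / Σ_j f_j over the vicinities |
| N (ignore) | MMAP reads are not placed |

The primary alignment is drawn from this distribution (per read, not per
sequence); other candidates become SAM secondary records. In U/F, reads
whose weights are all equal are placed uniformly when *n* ≤ 3 and otherwise
suppressed (marked unmapped), and reads past the 50-site cap are always
unmapped. The read's own tally contributions are excluded from its
vicinities, and tallies are computed once — no EM re-weighting.

## Worked example

Seven uniquely aligned reads sit in the vicinity of a two-position read's
first candidate site and one in the vicinity of the second:

```r
library(srnaplace)

mk <- function(prefix, positions) list(
  reads = data.frame(read_id = sprintf("%s%02d", prefix, seq_along(positions)),
                     sequence = strrep("A", 21L), n = 1L, overflow = FALSE),
  sites = data.frame(read_id = sprintf("%s%02d", prefix, seq_along(positions)),
                     reference = "chr1", pos = as.integer(positions),
                     strand = "+", length = 21L))
uA <- mk("uA", 1000 + 1:7)         # seven unique reads near site 1
uB <- mk("uB", 5000 + 1)           # one unique read near site 2
focal_r <- data.frame(read_id = "green", sequence = strrep("G", 21L),
                      n = 2L, overflow = FALSE)
focal_s <- data.frame(read_id = "green", reference = "chr1",
                      pos = c(1000L, 5000L), strand = "+", length = 21L)
aln <- alignment_groups(rbind(uA$reads, uB$reads, focal_r),
                        rbind(uA$sites, uB$sites, focal_s),
                        c(chr1 = 20000L))
grp <- alignment_groups(focal_r, focal_s, c(chr1 = 20000L))
cfg <- placement_config(mode = "U")
placement_probabilities(grp, build_tallies(aln, cfg), cfg)$p
#> [1] 0.875 0.125
```

The read is placed at site 1 with probability 87.5% — 7/(7+1) — and site 2
with 12.5%.

The full benchmark (simulate a 1-Mb genome with 200 loci and repeat
families, draw 50,000 reads, align once, place under each mode, score
against the simulation truth):

```r
res <- run_benchmark(library_config = default_library_config(n_reads = 50000L),
                     modes = c("R", "U"), seed = 1L)
res$comparison[, c("mode", "scope", "TP", "FP", "TN", "FN",
                   "precision", "sensitivity", "f1")]
#>   mode     scope    TP   FP TN  FN precision sensitivity    f1
#> 1    R       all 46989 3006  5   0     0.940       1.000 0.969
#> 2    R mmap_only  1096 3006  0   0     0.267       1.000 0.422
#> 3    U       all 49491  122  5 382     0.998       0.992 0.995
#> 4    U mmap_only  3598  122  0 382     0.967       0.904 0.935
```

On multi-mapping reads, unique-weighting placement is ~97% precise where
random placement is ~27% (about the average of 1/*n*); the cost is the 382
suppressed reads (false negatives) whose vicinities carried no signal.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "srnaplace", package = "srnaplace")`, with subcommands
`simulate`, `align`, `place`, `evaluate`, `benchmark`, e.g.:

```sh
srnaplace simulate  --outdir demo --n-reads 50000 --seed 1
srnaplace align     --genome demo/genome.fa --reads demo/reads.fastq --out demo/all.sam
srnaplace place     --in demo/all.sam --out demo/placed.sam --mode U --seed 2
srnaplace evaluate  --placed demo/placed.sam --truth demo/truth.tsv --outdir demo/eval
```

External all-alignment SAM (bowtie `-a` convention) can be placed the same
way via `read_alignment_sam()` / the `place` subcommand.

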