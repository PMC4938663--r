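---
title: "Local-context placement of multi-mapping small RNA-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-context placement of multi-mapping small RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant small RNA-seq libraries are dominated by 21–24-nt reads, and a large
share of them — heterochromatic siRNAs especially — derive from repetitive
sequence. Such a read aligns equally well to several genomic positions; we
call the number of equally best positions its MMAP-value *n*. The two
classical treatments are both unsatisfying: placing the read at a random
candidate position floods downstream locus calling with mis-placed reads,
while discarding all multi-mapping reads throws away much of the library
exactly where heterochromatic silencing is acting.

`srnaplace` implements a third option: use the *local context* of each
candidate position to weight the choice. The intuition is biological —
small RNA production is locus-concentrated, so the genomic neighbourhood of
a read's true origin usually contains other reads, many of them uniquely
aligned, while the other copies of the repeat are silent.

## The placement model

Alignment first enumerates **all** best (here: exact-match) positions of
every read on both strands, up to a reporting cap of `max_sites = 50`
positions; reads past the cap are marked unmapped. The reference is then
divided into 50-nt bins, and every alignment belongs to the bin of its
leftmost aligned nucleotide (no pro-rating across bin boundaries). One pass
over the all-alignment map produces two tallies per bin:

* `u_b` — the number of alignments of uniquely aligned reads (*n* = 1) in
  bin *b*;
* `f_b` — the fractional tally: every candidate site of every read adds
  1/*n*, so each read distributes a total weight of 1 across the genome.

The *vicinity* of a candidate site is the five-bin window centered on its
bin (≈250 nt), truncated at reference ends. For a read with candidate
sites *i* = 1…*n*, the placement probability of site *i* is

* **mode R** (random): `p_i = 1/n`;
* **mode U** (unique-weighting): `p_i = u_i / Σ_j u_j`, with `u_i` the
  vicinity sum of `u_b` around site *i*;
* **mode F** (fractional): `p_i = f_i / Σ_j f_j`, analogously over `f_b`;
* **mode N**: multi-mapping reads are not placed at all.

One site is then drawn from this categorical distribution to become the
read's **primary** alignment; all other candidates are written as secondary
records. Placement is per *read*, not per distinct sequence: one hundred
copies of the same sequence with probabilities (0.8, 0.2) will split
roughly 80/20 over the two positions.

Two guard rails apply in modes U and F. If every candidate's weight is zero
or all weights are equal (relative tolerance 1e-9, robust to the order in
which 1/*n* fractions accumulate), the read remains a pure guess: it is
placed uniformly when *n* ≤ 3 (`tie_suppression_threshold`) and otherwise
suppressed — marked unmapped — because a random guess over many positions
is almost surely wrong. Reads over the 50-site reporting cap are likewise
unmapped, under a distinct overflow status so that retention accounting can
see them.

### Self-exclusion

When a read's own candidate sites were part of the tally pass, its own
1/*n* contributions are subtracted from each vicinity before its
probabilities are computed. Without self-exclusion a read's own weight
inflates every one of its candidate vicinities equally at low coverage and
biases the two-candidate worked example away from the 73.7%/26.3% split
that defines mode F here (7 vs 1 + 3×0.5 after excluding the read's own
±0.5). Tallies are computed **once**; placement decisions never update
them. There is deliberately no EM-style re-weighting: the method is a
single-pass, local, auditable computation.

### Degenerate inputs and tie-breaks

Sites are ordered deterministically by (reference, position, strand), and
truncation at the reporting cap keeps the lexicographically first sites, so
identical inputs and seeds give byte-identical output. A zero U-mode
denominator is a tie, never a silent fallback to F — the modes stay
independent. Palindromic reads (their own reverse complement) report both
strand orientations at a position; both count toward *n*.

## The simulator

The generator builds the ground truth that real libraries cannot provide.
A synthetic genome (default: one 1-Mb reference, GC 0.36, roughly the
*Arabidopsis* value) carries 200 planted source loci in three archetypes:

* **hc-siRNA** (65% of loci): 200–1000-nt loci emitting primarily 24-nt
  reads from both strands, start positions uniform within the locus;
* **miRNA** (30%): 125-nt hairpin loci emitting plus-strand reads from a
  mature register (offset 20) and a miRNA\* register (the duplex partner
  with a 2-nt 3′ overhang) at a 10:1 ratio;
* **tasiRNA** (5%): 140-nt loci emitting 21-nt reads in phased registers
  from both strands (minus-strand registers offset by the 2-nt overhang),
  with register weights drawn once per locus.

Misprocessing is modelled as a per-read length deviation from the canonical
length (80% canonical, ±1 nt at 8% each, ±2 nt at 2% each, clamped to
20–25 nt) plus a ±1-nt shift of the 5′ end with 10% probability. Per-locus
abundances are log-normal (meanlog 0, sdlog 1) — heavy-tailed, as small RNA
expression is. Sequencing error is a single uniform substitution applied to
one read in 10,000. Every read ID encodes its origin
(`locus|reference|start|strand|serial`), and a TSV truth table is the
canonical record.

### Multi-mapping structure

Repeat families create the MMAP reads. A family is **one expressed
hc-siRNA host locus** whose central sub-segment (the repeat unit, ~50% of
the locus, at least 100 nt) is copied verbatim to *copy_number* − 1 silent
decoy positions elsewhere in the genome; by default 30% of hc-siRNA loci
host a family with total copy number uniform in 2–8. Reads wholly inside
the unit match the genome at exactly *copy_number* positions; reads
overlapping the unique flanks are unique and supply the vicinity signal.

This layout was a genuinely open design choice, and the obvious
alternative — making every family copy an expressed locus with identical
full-length sequence — turns out to remove the very signal the method
uses: if the entire locus is duplicated and all copies express, no read
from any copy is unique, every candidate vicinity is symmetric, and U-mode
reduces to ties and suppression. The host-plus-silent-decoys layout mirrors
what repeat-rich genomes actually look like to a small RNA aligner: most
genomic copies of a repeat are not active sRNA sources, and the active one
is surrounded by uniquely mappable production. Planted intervals are kept
at least 300 nt apart (beyond the five-bin window) so that one locus's
context does not leak into another's vicinity at desk-scale genome density.

### What the simulator does not model

No adapter remnants, quality-score error profiles, ligation bias, indels,
near-identical (diverged) repeat copies, or real-library abundance spectra.
Passing benchmarks on this generator therefore demonstrate the *mechanism*
— that local unique-read context recovers true origins when repeat copies
are transcriptionally asymmetric — not performance on any particular real
library, where repeat divergence and boundary fuzziness make placement both
easier (mismatch-discriminated copies) and harder (diffuse context).
Internal alignment is exact-match only; mismatch-tolerant alignments can be
supplied as all-alignment SAM (bowtie `-a` style) and placed identically.

## Evaluation

Against the truth table, each read is classified: placed at the exact true
(reference, strand, leftmost position) → **TP**; placed elsewhere → **FP**;
unplaced with no valid alignment position → **TN**; unplaced although a
valid position exists (suppressed, overflow, discarded) → **FN**.
Alignability is recomputed with the same aligner settings used for
placement, so an error-bearing read that happens to match elsewhere is
scored honestly. Precision is TP/(TP+FP), sensitivity TP/(TP+FN), F1 their
harmonic mean; metrics with zero denominators are undefined (`NA`), never
zero. Two false-negative rates are reported side by side: `fnr` =
FN/(FP+TP), the yield-based form usable on real libraries where TP and FP
cannot be told apart, and the conventional `fnr_standard` = FN/(FN+TP).
Metrics are also stratified by MMAP-value (exactly *n*, and cumulatively
≤ *n*), and a retention curve reports the library fraction placeable under
each MMAP cutoff (unalignable reads never retained; overflow reads above
every cutoff).

## Problem sizes and reproducibility

The package's own benchmark (`run_benchmark()`) simulates one library,
aligns it once, and places the identical all-alignment map under each mode,
so only the placement policy differs between arms. The default comparison
uses the 1-Mb / 200-locus genome with 50,000 reads — large enough that
MMAP-read precision estimates have standard errors around a percentage
point, small enough to run in well under a minute on one CPU. Full-scale
library composition checks use the complete five-million-read default.
Every stage seed derives deterministically from one global seed; identical
configurations and seeds give byte-identical FASTA/FASTQ/TSV/SAM output.

On the default benchmark, U-mode precision on multi-mapping reads is
routinely above 90% while random placement sits near the expected 1/*n*
average (20–30%), at a sensitivity cost from tie suppression concentrated
in reads deep inside repeat units — the trade the method is designed to
make. Mode F lands between U and R: its fractional tallies let the MMAP
reads themselves vote, which softens the unique-read signal.

## Limitations

* Exact-match internal alignment only; divergence between repeat copies is
  not exploited (import external SAM for that).
* The 250-nt vicinity is tuned to plant-style compact sRNA loci; diffuse
  loci spread over kilobases would need wider windows.
* Suppression trades sensitivity for precision by design; libraries
  dominated by very-high-copy repeats will see low retention.
* The simulator's register offsets (miRNA mature at 20, 2-nt overhang
  geometry) are fixed conventions, configurable but not fitted to any
  species.
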