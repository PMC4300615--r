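---
title: "Detecting fusion transcripts from split and discordant RNA-seq alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion transcripts from split and discordant RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refusion)
```

## The problem

A genomic rearrangement that joins two genes can be transcribed into a
fusion mRNA.  In paired-end RNA-seq against the reference genome such a
transcript cannot align contiguously; it betrays itself through chimeric
(split) read alignments, soft-clipped partial alignments, and discordant
mate pairs.  Each signal alone is noisy — clipped reads arise from adapter
read-through and low-quality tails, discordant pairs from mapping errors and
structural polymorphism — so a caller must *combine* them, reconstruct the
junction sequence explicitly, and then re-quantify support against that
reconstruction.  `refusion` implements this strategy as four stages, each
exposed as ordinary R functions so every decision rule can be tested in
isolation.

## Stage 1: the relaxed breakpoint scan

Alignments are classified per fragment: a read is **chimeric** when its
segments span two chromosomes, two strands, or a distance beyond the maximum
allowed intron (`max_intron`, default 200 kb — beyond the longest credible
human intron); a pair is **discordant** under the same three conditions
applied to the mates; a read is **partial** when clipped sequence remains
unexplained.  Breakpoint calls are tiered by strength of evidence:

| tier | evidence | threshold |
|------|----------|-----------|
| 1 | chimeric read, called at the split point | — |
| 2 | partial alignment, discordant mate, unmapped part ≥ L_min with no N | ≥ t₁ = 2 consistent neighbours |
| 3 | partial alignment with shorter clip, discordant mate | ≥ t₂ = 3 consistent neighbours |
| 4 | entirely aligned discordant pairs agreeing on one fusion point, called at the farthest 3′ extension | group of ≥ t₃ = 4 |

`L_min = clamp(l/5, kmer, 1.5·kmer)` ties the minimum useful clip to the
mapper seed size (`kmer ≤ 16`, default 15): clips shorter than a seed cannot
be independently located, and a fifth of the read length is required once
reads are long enough.  *Consistent with X* is implemented as: same
(chromosome, strand) on the anchored side, same mate (chromosome, strand) on
the partner side, and anchor positions within the ±200 bp neighbour window —
the only window size the procedure defines.  Calls inside repeat annotation
are removed, the rest are single-linkage grouped within 200 bp, the
strongest call represents each group (ties: more support, then smaller
coordinate), and every group seeds a candidate region of ±250 bp, clipped at
chromosome ends but never discarded.

The scan is vectorised but intentionally mirrors a literal reading of the
criteria; the test suite keeps an independent, loop-per-read oracle and
checks equality on hundreds of randomised alignment sets, plus monotonicity
in t₁–t₃ (raising a threshold can only remove calls).

## Stage 2: regional assembly

From each region the *abnormal* read pairs — discordant pairs, singletons,
and partially or chimerically aligned reads with a segment overlapping the
window — are harvested together with their mates (wherever mapped, or
unmapped).  Proper concordant pairs are excluded: they carry no junction
information and only add repeat structure.

The assembler is a deliberately minimal single-k de Bruijn graph: canonical
k-mer counting, pruning of k-mers below `min_kmer_cov = 2` (a singleton
k-mer at 20–60× regional coverage is almost surely an error), clipping of
dead-end tips shorter than `2k`, compression of unbranched paths, and
deterministic output ordering (support, then sequence).  `k = 21` (odd, so
no k-mer is its own reverse complement) is a conventional choice for 100 nt
reads: long enough that random 21-mers do not recur in a ±250 bp
neighbourhood, short enough that error-free reads still tile junctions.
Multi-k merging and isoform-aware traversal of full transcriptome
assemblers are not reproduced — a junction-spanning contig from a 500 bp
neighbourhood does not need them, and regional read sets are small.  The
assembler is pluggable: `detect_fusions(contigs_from = "contigs.fa")`
substitutes externally assembled contigs.

## Stage 3: contig re-alignment, chaining, junction detection

Contigs are re-aligned by exact seeds (default `min_seed = 15` nt, placed
every seed-length along both strands) extended ungapped under an X-drop rule
with +1/−1 scoring.  Contig intervals that map to more than one genomic
locus within 95% of the best score are removed as non-unique — the classic
defence against paralogy and segmental duplication.  Remaining segments are
chained by dynamic programming (free genomic jumps, so introns cost
nothing); the two best distinct chains give aggregate scores q₁ ≥ q₂ for a
contig of length q₀ and the alignment score

$$Q = e^{(q_1-q_0)/10} - e^{(q_2-q_0)/10} \in [0, 1],$$

which is 1 for a perfect unique alignment and 0 when the best two chains
tie.  Segment overlaps are subtracted once from the chain score so q₁ never
exceeds q₀.

A best path whose consecutive segments belong to two different genes is a
putative fusion junction.  Two numerical subtleties matter here:

* **Extension overshoot.**  An ungapped extender runs past the true
  junction whenever the partner locus happens to continue matching (a
  biased random walk that reaches +1 with probability ~1/3 on random
  sequence), so the *raw* overlap between the two partner segments
  overstates the microhomology.  Chaining therefore tolerates 25 nt of
  slack above the documented cap, and the 15 nt microhomology rule is
  enforced on the *refined* overlap instead: around the split, each
  position is scored for agreement with the left and the right locus, and
  the width of the plateau of the optimal split equals the true homology.

* **Breakpoint canonicalisation.**  Within a microhomology run the
  breakpoint is genuinely ambiguous — several (breakpoint5, breakpoint3)
  pairs produce the same transcript.  Caller and simulator share one
  convention: the junction is placed maximally 3′-wards in the fused
  transcript (ties in the split score resolve towards the transcript-5′
  partner).  Without a shared convention, "exact" breakpoint recovery is
  ill-posed.

The 5′/3′ partner order follows transcriptional orientation: the upstream
partner is the segment aligned in the sense of its gene.  Breakpoints inside
repeat or self-chain annotation set per-side flags; `Q < 0.5` sets `low_Q`.
The 15 nt rule is read as a maximum *tolerated* overlap (microhomology
tolerance), the only reading under which larger sharing — which makes the
two-gene assignment unreliable — is rejected.

## Stage 4: support, scores, filters, classification

Improper pairs (the region's abnormal pairs plus initially unmapped pairs)
are re-aligned to the junction contig — exact occurrence first, local
alignment as fallback.  A read is **spanning** support when it crosses the
fusion point with at least 13 nt aligned on both sides (distances Lᵢ and
Rᵢ); otherwise a pair whose mates sit on opposite sides is **encompassing**
support.  Reads with identical alignment offsets (PCR duplicates) count
once, and each pair contributes to one category only.

Junctions with at least two non-redundant supporting reads are reported and
ranked by, in order: the Spanning Score
`SS = N − Σ |Lᵢ−Rᵢ|/(Lᵢ+Rᵢ)` (rewards many, balanced junction reads; a read
clinging to one side contributes almost nothing), the encompassing count,
and Q.  The final filter removes candidates with total support below 5, SS
below 1, or *both* breakpoints inside repeat/self-chain annotation — the
three conditions are independent removal criteria, so any one suffices.
Isoform junctions sharing the ordered gene pair merge into one record
(best-ranked junction as representative, all breakpoints listed); the
swapped orientation is a different fusion and never merges.  Type is
Intra/Inter by chromosome; frame compares CDS codon phase across the
junction on the longest-CDS transcript of each partner (`offset5 ≡ offset3
mod 3` is in-frame; breakpoints outside any CDS give NA).  The choice of the
longest CDS is a convention — transcript selection is otherwise
unconstrained.

## The simulator: what it emulates and what it does not

`simulate_run()` emulates a 2×100 nt paired-end protocol: Normal(250, 30)
inserts, 0.1% substitution errors, uniform fragment starts, 30× wild-type
coverage with a per-fusion expression multiplier (default 2×).  The toy
genome (uniform ACGT; default 500 kb + 2 × 60 kb) carries forward-strand
genes of 2–5 exons (250–450 nt, introns 0.2–2 kb) with CDS and UTRs, a
fixed 300 nt motif tiled as the repeat track, and a duplicated 400 nt
segment as the self-chain track.  Fusions join spliced exonic portions at
CDS-internal breakpoints chosen at least 60 nt (falling back to 40/25 nt
for small genes) from exon boundaries, with codon phases drawn to produce
the requested IF/OF label; truth breakpoints are canonicalised exactly as
the caller canonicalises (see above).  Each retained side of a fused
transcript is kept at least one insert length (250 nt) long: in paired-end
sequencing only the fragment ends are read, so a junction closer than that
to a transcript end falls into the unsequenced gap of most fragments and
cannot accrue spanning reads — the geometry any study design must respect
for junctions to be observable.  Alignments are emitted by an
idealised mapper — placement by construction from the truth, spliced
N-CIGAR records, junction-crossing reads as primary-plus-supplementary
splits (or a clipped partial when one side is under the 15 nt seed) — so
that tests isolate the caller's logic from mapper noise.

Two intra-chromosomal test genes sit > 200 kb apart, beyond the default
maximum intron, which is what makes an intra-chromosomal fusion visible to
a distance-based discordance definition.  Real intra-chromosomal fusions
are often inversions, visible through strand flips instead; the v1
generator does not simulate minus-strand genes, so that code path is
exercised only at the unit level.  Other simplifications: no quality-score
model, no indels, no empirical error profile, no PCR-duplicate structure
beyond exact duplicates, and — because the mapper is idealised — no
spurious clips or mismapped reads.  A clean report on simulated data
therefore demonstrates the correctness of the decision rules, not the
false-positive rate on real libraries, where mapper artefacts and
reference incompleteness dominate.

## Problem sizes and determinism

The test suite runs the full pipeline on 20 simulation seeds (two planted
fusions each — one Intra/in-frame, one Inter/out-of-frame — plus matched
fusion-free runs), recovers all 40 events at exact breakpoints with correct
labels and zero false calls, checks the assembler on 100 random templates
of 200–2000 nt at 20× error-free coverage, and compares the breakpoint scan
against the naive oracle on 200 random record sets.  These sizes keep a
full run on a single core within minutes while covering every rule
boundary.  The pipeline is a pure function of its inputs: reports are
byte-identical across repeated runs and across worker-pool sizes (regional
assemblies are dispatched in region order, and nothing downstream depends
on scheduling).

## Known limitations

* Splice-aware alignment *within* a gene is not modelled; exons align as
  separate chained segments, which suffices for junction detection but
  does not annotate the fusion transcript's exact exon structure.
* Genes overlapping on opposite strands can both claim a segment; the
  larger overlap wins, which may misassign single-exon fragments inside
  read-through regions.
* Frame classification trusts the annotated CDS of the longest-CDS
  transcript; fusions spliced to non-reference exons are classified NA or
  wrongly phased.
* The support pool for a junction is drawn from its source region plus
  unmapped pairs; support mapping exclusively near the partner breakpoint
  of a very asymmetric event could be undercounted.
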