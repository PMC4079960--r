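---
title: "Methods: junction filtering, event classification and differential splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction filtering, event classification and differential splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescope)
```

## Scope and model

splicescope analyses alternative splicing (AS) from spliced short-read
alignments in a junction-centric way: the unit of evidence is the
exon–exon junction, identified with its intron interval, and every
downstream call — event classification, intron retention, differential
testing — is built from junction, intron and exon read counts. Read
alignment itself is out of scope: the package consumes alignments (SAM
with CIGAR `N` gaps) or junction files (TopHat-style BED12) produced by
any spliced aligner.

Coordinates are 1-based and inclusive throughout, matching the
Bioconductor containers the package is built on (IRanges, GenomicRanges,
rtracklayer, Biostrings). A junction key is the intron interval
`chrom:first_base-last_base`; keys are strand-agnostic so that known/novel
matching is exact, with strand carried as an attribute.

## Junction filtering and its calibration

A junction-spanning read has two anchors; its *overhang* at the junction
is the smaller one, counting only aligned (M/=/X) bases on each side of
the gap. A junction's overhang is the maximum over its supporting reads,
and "uniquely mapped" is operationalised as a MAPQ floor (default 10,
configurable — aligners encode uniqueness differently and the package
does not silently guess).

Spurious junctions from non-specific or erroneous alignment are short on
both statistics. The filter is calibrated against *decoy junctions*:
annotated exons from two different chromosomes spliced in silico, 90 nt
on either side of the joint (180 bp total). Any read support a decoy
attracts is false by construction. With 101 bp reads, every placement
that spans the joint has both anchors ≥ 11 bp (`read_len − flank_len`),
so decoy support is never censored by geometry; what the calibration
shows is that decoy-supported junctions concentrate at overhangs ≤ 20 bp
and single-read coverage. The default filter — overhang strictly greater
than 20 bp AND at least 2 supporting reads — removes essentially all
decoys while retaining the vast majority of annotated junctions.
`calibrate_filter()` reports both distributions and the removal/retention
fractions; decoy exon sampling is seeded, samples exons of at least one
flank length, preserves orientation (suffix of one exon + prefix of the
other) and draws pairs with replacement.

Between-condition comparisons assume equal depth;
`subsample_alignments()` draws an exact uniform subsample (pair-level
when the library is paired, so mates are never orphaned) with a fixed
seed. `library_qc()` provides the exonic/intronic/intergenic read split,
a relative-position coverage profile (40 bins, 5'→3') and a
gene-detection saturation curve (10 evenly spaced depths, 3 averaged
repeats by default).

## Event classification

Events are derived from the confident junction set plus annotated exon
structures, per gene (junctions are assigned to the genes whose span
contains them; the longest containing gene is the primary assignment):

* **CE/CCE** — an exclusion junction bridging one exon (CE) or a chain of
  ≥ 2 junction-connected exons (CCE) that also have inclusion junctions
  from the same flanks.
* **MXE** — two disjoint exons sharing outer anchors, each with inclusion
  junctions, whose co-inclusion junction is absent from the confident set.
* **A5SS/A3SS** — ≥ 2 junctions sharing one anchor and differing at the
  other site; which splice-site side varies follows from strand (the
  genomic-right boundary is the acceptor on `+`, the donor on `−`).
* **AFE/ALE** — the shared-anchor pattern where every varying site
  coincides exactly with a boundary of distinct, *non-overlapping*
  transcript-first (AFE) or transcript-last (ALE) exons. The
  non-overlap requirement is deliberate: two annotated first exons that
  share a start but differ at the donor are an alternative 5' site
  within one exon, not an alternative first exon.

The *dominant* site of an alternative-site event is the annotated one
when exactly one competing site is annotated, otherwise the site with the
highest read support (ties resolved toward annotated, then leftmost).
Offsets of alternative sites are signed in transcript orientation:
positive = downstream of the dominant site, which for a 5' splice site
means into the intron.

**Intron retention** is called from intronic coverage only: an
*intron-read* aligns entirely within the intron with no gap;
boundary-spanning reads are reported but never counted toward the
thresholds. A call requires at least 5 intron-reads (inclusive) and
strictly more than 80% of intron bases covered — the inclusive/strict
asymmetry is intentional and tested at the boundary. Whether the breadth
is assessed per library or pooled is the caller's choice; the default is
whatever coverage table is passed in (per library in the pipeline).

**PTC prediction** splices the variant transcript in silico (intron kept
for IR; exon inserted or removed for CE), maps the annotated CDS start
into it and translates with the standard nuclear code; a stop codon
strictly upstream of the annotated stop is a PTC. Events outside the CDS
leave the frame untouched and are reported as 5'UTR/3'UTR with
`ptc_introduced = FALSE`; transcripts without CDS annotation give an
explicit indeterminate verdict. No NMD 50-nt rule is applied — PTC
presence, not NMD targeting, is the claim.

## Differential splicing

Each treatment is compared with the control independently on the 2×2
table `[[event_ctrl, exon_ctrl], [event_trt, exon_trt]]`, where event
reads are junction reads (intron reads for IR) and exon reads come from
the event's flanking exons (both flanks summed for IR and CE, the
shared-anchor exon for A5SS/A3SS). `fisher_exact_2x2()` computes the
two-sided p-value by summing hypergeometric probabilities at most as
probable as the observed table — the same definition as R's
`fisher.test`, which together with a `lchoose`-based enumeration serves
as the independent oracle in the tests. The reported odds ratio is the
sample `ad/bc` (with `Inf` allowed), not the conditional MLE.

Thresholds are raw p-values by design — `p < 0.05` for junction-based
events, `p < 0.001` for intron retention — and no multiple-testing
correction is applied by default (a Benjamini–Hochberg column can be
added by the caller from the returned p-values). Events observed in only
one condition cannot produce a finite Fisher p against a zero row; the
uniqueness rule calls them significant with `p := 0` when supported by
at least 5 junction reads, or for IR by at least 5 intron reads with
breadth above 80%, in the condition where they appear. Events with zero
event reads in both conditions are returned as explicitly untestable.

The global comparison contrasts, per event type, the junction reads
assigned to the type against the remainder of the condition's junction
reads, again with Fisher tests; it refuses unequal library depths unless
overridden, because the absolute counts are only comparable after
subsampling.

## The synthetic experiment

The generator exists to make every stage falsifiable without external
data. Its defaults describe a small experiment chosen to keep the test
suite fast while exercising everything: 4 chromosomes, 40 genes of 6–8
exons (exons 120–260 bp, introns 90–160 bp), 101 bp reads, a planted mix
of 6 CE, 8 A5SS, 8 A3SS, 2 MXE, 2 CCE, 2 AFE, 2 ALE and 8 IR events, a
differential fraction of 0.3 with inclusion shift Δψ = 0.3 (alternating
direction, baseline ψ = 0.4 for junction events and 0.6 for IR), and a
10% artifact rate of spurious junctions with ≤ 20 bp anchors and
single-read support. Every intron — annotated or planted-alternative —
begins GT and ends AG in transcript orientation, so dinucleotide
extraction must return exactly GT/AG; alternative-site offsets are drawn
concentrated at ±4 bp. Alternative first/last exons are emitted as a
second annotated transcript (as real annotations do), making AFE/ALE the
only planted events that are *not* novel; a quarter of IR hosts retain
their 5'UTR intron and the rest a CDS intron with an in-frame stop
planted at the correct codon boundary, fixing the PTC truth.

The count model is deliberately simple: event reads are
`Binomial(depth, ψ)` against a per-condition event depth (default 300)
and exon reads are the remainder of that depth. This makes the null of
the differential test well defined — two binomials with equal ψ — so the
type-I error of the Fisher test can be measured against its nominal
level; the attained level sits slightly below 0.05 (the usual
conservatism of the exact test at finite counts) and within three
binomial standard errors of it at the simulation sizes used. No
overdispersion, GC bias, sequencing error or expression-level realism is
modelled: passing tests demonstrate the correctness of the pipeline's
logic under its own generative assumptions, not performance on real
libraries. Alignment simulation is error-free and single-end (a paired
mode duplicates mates at a fixed insert for testing pair-level
subsampling); junction reads place the left anchor uniformly on
`1..read_len−1`, so anchor minima never exceed 50 bp and, at the default
depth of 12 reads per junction, the probability that a true junction
fails the overhang filter is `0.4^12 ≈ 2e-5`.

## Numerical and design choices

* Ties in the Fisher summation are compared with a `1 + 1e-7` relative
  tolerance, matching `fisher.test`'s guard against floating-point
  misclassification of equal-probability tables.
* Determinism: every random step (decoy sampling, subsampling, the
  generator, permutation draws) takes an explicit seed and restores the
  caller's RNG state, so pipeline outputs are pure functions of (inputs,
  config, seeds) — re-running a stage reproduces its files byte for byte.
* Degenerate inputs are explicit: empty annotations load to empty
  objects; an all-zero Fisher table returns p = 1; an event with no reads
  anywhere is "untestable", not p = 1; zero CE events make the
  co-occurrence test "untestable" rather than returning a fraction of
  zero exons.
* Problem sizes in the tests and the acceptance script — a 40-gene
  genome, 2 000–20 000 null events, 200 permutation runs, the exhaustive
  Fisher sweep over margins ≤ 30 (~164 000 tables) — were chosen as the
  smallest sizes at which the measured quantities are stable to well
  within their tolerance bands.

## Known limitations

Junction-to-gene assignment uses span containment with a longest-gene
primary rule; read-through junctions across adjacent genes are not
modelled. Classification reports junction-supported patterns and does not
quantify inclusion (no PSI estimation or isoform-level quantification).
The co-occurrence expectation depends on the chosen exon universe and
permutation count, which are configuration, not constants. Junctions
whose strand cannot be resolved from annotation or host gene are skipped
by the dinucleotide analysis with a warning.
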