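---
title: "circkit: models, decision rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: models, decision rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

## The problem

Back-splicing ligates the 3' end of a downstream exon to the 5' end of an
upstream exon of the same transcript, producing a covalently closed
circular RNA. In an RNA-seq library the only direct evidence for a circle
is a read whose two halves map in *reversed* genomic order — the
head-to-tail junction read. `circkit` implements the full desk-scale
analysis around that signal: simulation with known truth, junction
calling, annotation, circular-to-linear quantification, expression
tiering, junction-ORF prediction, and ΔΔCt validation modeling.
Everything below is computed by the package's tests or its pipeline; no
empirical claim is made that they do not check.

## Coordinates and catalog conventions

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
and BED12 are converted on read/write. A circle's `start` is the first
base of its 5'-most genomic exon and `end` is one past its 3'-most base —
a strand-independent genomic span with strand carried separately.
Identifiers are `"<chrom>:<start>-<end>:<strand>"`, a synthetic stand-in
for database accessions; whether public circRNA databases use 0- or
1-based starts is deliberately not claimed here, only documented for this
package's files.

## The synthetic world

The generator states one fixed world rather than a dial to be tuned:

* 20 genes on one chromosome, 3–6 exons of 80–300 nt, introns 60–400 nt,
  every intron `GT...AG` on the transcript strand, strands random, genes
  non-overlapping. Minus-strand genes are built on the transcript strand
  and inserted as reverse complements, so splice signals are correct on
  both strands.
* 100-nt single-end reads, 100 fragments per locus (2,000 fragments for
  the 20-gene acceptance library), substitution errors only, base
  qualities fixed at Q40. Paired-end reads, coverage/GC bias, rRNA
  contamination and quality modeling are intentionally absent: the anchor
  method operates per read, and these realism features would not change
  what the tests establish.
* Planted circles occupy contiguous *internal* exon blocks. This is a
  biological constraint, not a convenience: the back-splice acceptor needs
  an upstream intron to supply the `AG` and the donor a downstream intron
  for the `GT`, so terminal exons cannot contribute junction boundaries.
  Rings shorter than the read length are excluded at planting time
  (`min_spliced_length`), honoring the simulator's precondition that a
  read not wrap more than once; rolling-circle concatemers are not
  simulated, consistent with concatemers being ignored in the validation
  assays this models.
* The circular fraction at a planted locus defaults to 0.5 — a deliberate
  middle value: published circular-to-linear ratios at validated loci
  range from well below 1 to far above it, and 0.5 exercises both
  junction and linear boundary counts at comparable depth.
* Circular fragments sample the ring uniformly; a read starting within
  `read_length - 1` nt of the ring end wraps the junction, so the expected
  junction-read share is `(L_read - 1)/L_ring`. The test suite checks the
  observed share against this binomial oracle at depth 10,000.
* RNase R digestion is modeled as independent per-fragment survival
  (default 0.1 for linear, 1.0 for circular molecules). The survival
  rates are simulator knobs, not literature claims — no quantitative
  digestion efficiency is published for the assay modeled here.
* Truth tags ride in read names (`id:class:transcript:circ_id:juncflag:
  crossings`), so every downstream count can be checked against
  construction.

A green test on this world establishes that the algorithms are correct on
clean, repeat-free, exactly-matching data. It does *not* establish
performance on real libraries with repeats, sequencing errors at terminal
anchor bases, or isoform complexity; those belong to the real pipelines
this package models at desk scale.

## Detection decision rules

Anchors are the first and last 20 nt of a read, matched exactly against a
k-mer index of both genome strands. 20 nt is the published default of the
anchor-based detection family this follows; exact matching (0 mismatches)
keeps the desk-scale contract crisp. A call requires:

1. both anchors uniquely placed, same chromosome, same strand;
2. reversed genomic order (tail anchor upstream of head anchor);
3. genomic span ≤ 100 kb (`max_span`, bounding trans-splicing artifacts);
4. after maximal extension of both anchors toward the breakpoint, exactly
   one split point whose acceptor side is preceded by `AG` and whose
   donor side is followed by `GT` on the transcript strand (`AC`/`CT` in
   forward-genome letters for minus-strand candidates).

Several signal-consistent breakpoints, or consistency on both strands,
reject the read as ambiguous rather than guessing. Unlike the real
pipelines there is no prior subtraction of contiguously mapping reads: at
desk scale every read enters the detector and linear reads simply fail
the reversed-order test. This is a documented deviation that changes
nothing on repeat-free synthetic genomes.

Collapsing groups calls by (chrom, strand, acceptor, donor) and counts
*distinct read sequences*. "Two unique reads" is read literally as
deduplicated sequences: five copies of one fragment are one unique read,
and the candidate is dropped below the minimum expression threshold of
two. Output is invariant to read input order.

## Annotation

Priority when features overlap: exon-bounded same-strand host (both
junction boundaries within ±2 nt of exon boundaries) → `coding_exon` if
the host has a CDS (UTR exons count as coding-gene territory) else
`noncoding_gene`; wholly intron-contained same-strand → `intronic`;
opposite-strand overlap only → `antisense`; no overlap → `intergenic`.
The ±2 nt tolerance absorbs breakpoint-extension jitter; zero tolerance
makes the exon-boundary rule needlessly brittle. Two open points the
literature leaves unstated were decided as follows: a candidate exonic in
one transcript and intronic in another is exonic (the priority order
above), and among several exon-bounded hosts the one minimizing spliced
length wins, tie-broken lexicographically — a minimal-assumption choice
that is deterministic under transcript reordering. Same-strand exonic
overlap *without* boundary coincidence falls back to the coding/noncoding
category of the maximally overlapping host. Spliced length is the exonic
intersection of the circle span; genomic length the full span; spliced ≤
genomic with equality exactly when the span contains no intronic bases.

## Quantification

`CLR = reads_circular / max(linear_5p, linear_3p)`, with the denominator
replaced by the pseudocount 1 only when *both* linear counts are zero —
the literal reading of "where no linearly spliced reads were detected",
and the only reading consistent with a published worked example in which
one linear count is zero yet the other is used (27 circular, 29 vs 0
linear → 0.9). Report columns round half-up to one decimal, matching the
printed convention (base R's round-half-even would print 0.85 as 0.8);
full precision is kept internally. A linear read must clear the splice
boundary by ≥ 5 nt on each side to count, mirroring junction-overlap
logic; a read crossing both boundaries increments both counts (the
single- vs double-count choice is unstated in the source material;
both-increment is the documented decision). TPM is the standard
length-normalized composition,
`1e6 * (c_g/l_g) / sum_h(c_h/l_h)`.

## Tiers

Per sample: detected = ≥ 2 unique junction reads; high = detected and
within the top `ceiling(f * n_detected)` by raw junction read count, with
`f = 0.10` (0.05 for platelet-like samples). The top pool is computed
within each sample's detected set — the class definitions are per-sample,
and no cross-tissue normalization is attempted (there is no accepted
circRNA housekeeper). Ceiling rather than floor keeps at least one high
circRNA in small samples; ties at the cutoff break by higher CLR then by
id, so the partition `|high| = ceiling(f * n_detected)` is exact and
deterministic. The plotted matrix keeps only rows high in ≥ 1 sample;
clustering is complete linkage on Manhattan distance over the ordinal
codes 0/1/2 — no linkage or metric is named in the source material, and
this pair is the least-surprising choice for small ordinal matrices.

## Junction ORFs and peptides

The ring sequence is doubled and translated in three frames; maximal
AUG-to-stop ORFs whose nucleotide span covers the junction are reported.
AUG-only initiation and a length cap of `max_loops = 1` ring length are
the package's decisions (the source material states no ORF parameters);
the cap bounds stop-free frames, consistent with ignoring rolling-circle
concatemers, and capped ORFs are flagged `no_stop_in_circle`. An ORF (or
truncated ORF) "crosses" the junction iff its span strictly contains the
first base after the junction — an ORF ending exactly at the junction
does not. Tryptic digestion cleaves after K/R except before P; peptides
keep only fragments whose codons straddle the junction, within 7–35 aa
(typical tryptic observability) and 0 missed cleavages by default.
Observed-peptide matching is exact string comparison, and peptides that
match hosts but not the junction database receive the `non_junction`
verdict — the outcome class reported for the platelet translation
experiment this models. Correctness is established against an exhaustive
start×frame oracle on random rings, including short rings that stress the
truncation boundary.

## ΔΔCt

ΔCt = mean assay Ct − normalizer Ct, where the `spike_housekeeper` policy
averages the spike-in and housekeeper channel Cts (arithmetic mean of Ct
= geometric mean of abundances; whether the original assays averaged or
chained the two normalizers is unstated — averaging is the documented
choice) and the `28S` policy uses the rRNA channel, the variant used for
patient samples. Fold = `2^-ΔΔCt`. The group test is a classical
equal-variance Student t by default (that is the test named in the
figure legends), Welch behind a flag; technical replicates are pooled as
individual observations, matching the legend's "across samples and
replicates" — with the explicit caveat that this inflates n relative to a
per-sample analysis. Degenerate zero-variance groups return t = 0, p = 1
when identical and p = 0 when perfectly separated, so noise-free
simulations are well-defined. Calibration is verified by 2,000-rep null
simulation (type-I error within [0.035, 0.065] at nominal 0.05) and
recovery of a planted fold-4 effect within 5% relative bias at Ct noise
0.2 and n = 6 per group.

## Pipeline determinism

Stages exchange data only through files; every stage writes a provenance
sidecar (parameters, seed, input/output MD5 checksums) and the whole
pipeline is byte-identical under a fixed seed. All randomness flows from
the single mandatory seed; child seeds are derived arithmetically and
kept below 2^31.

## Known limitations

* Exact-match anchors: a single sequencing error in a terminal 20-mer
  loses that read; there is no mismatch budget or indel tolerance.
* No multi-mapping rescue, paired-end logic, or lariat-circle class.
* The published catalog-level numbers (total catalog size, novelty
  fraction, the 82.9/2.2/5.4/6/1.1% category split, per-tissue counts)
  depend on real libraries and a real genome annotation and are out of
  scope by design; the category machinery is instead verified on planted
  truth.
* Amplification-efficiency correction, standard curves and multiple-
  testing control are out of scope for the ΔΔCt module.
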