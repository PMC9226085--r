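---
title: "Methods: linking intronic A-to-I editing loss to circRNA formation"
author: "circedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking intronic A-to-I editing loss to circRNA formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological model

ADAR enzymes deaminate adenosine to inosine (A-to-I) in double-stranded RNA.
Inosine base-pairs like guanosine, so an edited site appears in RNA-seq reads
as an A>G mismatch against the genome — or as T>C when the editing substrate
lies on the minus genomic strand. The preferred ADAR substrates in human
transcripts are inverted pairs of intronic Alu elements, whose base-pairing
also promotes back-splicing: the head-to-tail joining of a downstream exon's
3' end to an upstream exon's 5' start that produces a circular RNA (circRNA).
Editing of the paired Alus weakens the duplex; loss of editing therefore
favours circularisation. This package implements the computational arm of
that hypothesis as one testable pipeline: call editing sites, detect
back-splice junctions, overlap editing with the introns flanking each
back-splice site (BSS), and count the strand-orientation classes of Alu pairs
in those flanking introns, comparing a control group against a disease
("HF", heart failure) group throughout.

## Editing-site calling

For each sample, aligned RNA reads are piled up over the genome. A position
is a candidate editing site when

* exactly one non-reference base reaches `min_alt_reads` (default 3),
* total depth reaches `min_depth` (default 5), and
* all remaining non-reference bases together stay at or below
  `max_noise` × depth (default 0.05) — the sequencing-error guard.

The editing ratio is alt reads / depth. Bases below `min_base_quality`
(default 25), reads below `min_mapping_quality` (default 20) and positions
within `trim_ends` (default 5) bases of a read end are masked before
counting; the end-trim is a standard artifact guard and can be disabled.
These thresholds follow RNAEditor-class callers and are all exposed as
arguments.

Candidates are then filtered against SNPs twice. Any candidate at a position
in the known-variant VCF is removed. When matched DNA alignments are
available, a candidate whose DNA alternative-allele fraction exceeds
`max_dna_alt_fraction` (default 0.1) at DNA depth ≥ 10 is removed as a
genotype call: a heterozygous SNP shows the variant in DNA at about 0.5,
while a true editing site never appears in DNA. Surviving sites are typed
into the twelve substitution classes on the genomic plus strand; A>G and T>C
together constitute the A-to-I readout. Sites are called per sample and
aggregated afterwards, never jointly.

We do not reimplement BLAT-style realignment filtering; at the scale of the
synthetic genomes every anchor is placed by exact search and the DNA check
covers the genotype confounder, so a realignment stage would have nothing to
act on. This is a known limitation for noisy real data.

## Back-splice junction detection

Reads that fail to map linearly are the circRNA substrate. The first and
last `anchor_len` (default 20) bases of each read are aligned independently
to the genome by exact k-mer search on both strands, with a one-mismatch
fallback. A read is a back-splice candidate when both anchors map uniquely
and the head anchor lands *downstream* of the tail anchor — the reverse of
linear order. Anchors are then extended inward until two genomic segments
explain the whole read. When breakpoint homology leaves several consistent
splits, the split placing canonical splice dinucleotides — GT immediately
after the donor and AG immediately before the acceptor, on the junction's
strand — is chosen; if none exists the leftmost consistent split is used and
the junction is labelled `other`. This tie-break is what makes
exact-coordinate tests deterministic.

Junction-level filters mirror the established circRNA-discovery practice:
at least two unique supporting reads (identical read sequences collapse to
one), both anchors unique with a score margin of at least two matches over
the second-best locus, and a genomic span below 100 kb. Filter failures are
recorded, not silently dropped. Every junction is finally verified by
searching the raw reads for an 80-bp back-spliced probe — the 40 nt before
the donor joined to the 40 nt after the acceptor, allowing two mismatches.
The 40/40 split is the neutral symmetric reading of an 80-bp probe and is
configurable. The anchor-uniqueness margin stands in for a mapping-quality
cutoff: exact-match uniqueness is the desk-scale equivalent of the MAPQ
filtering used by find_circ-lineage pipelines.

## Integration and statistics

BSS-spanning read counts are normalised per million linearly mapped reads;
host-gene expression is summarised as FPKM over the gene span. Group
comparisons all pass through one normality-gated decision tree: values are
first tested for Gaussian distribution (Shapiro–Wilk at α = 0.05; chosen
because base R ships it as the standard normality test — any gate with
reasonable power behaves equivalently at these group sizes); if every group
passes, Student's t-test (two groups) or one-way ANOVA with Tukey's post hoc
(more); otherwise Mann–Whitney U (two unpaired), Wilcoxon signed-rank
(paired) or Kruskal–Wallis. Correlation follows the same gate: Pearson when
both vectors pass, Spearman otherwise. Groups smaller than three values skip
the gate and default to the nonparametric branch with a warning.

Differential circRNA calls use p < 0.05 with no multiple-testing correction
by default, matching the convention of a volcano plot with a raw-p dashed
line; Benjamini–Hochberg is available as an option. A regulated circRNA
whose host mRNA is itself unchanged (p ≥ 0.05) is classified
host-independent.

For every regulated circRNA the introns immediately flanking the BSS are
resolved *structurally* — the intron adjacent to the breakpoint exon, in
host-gene orientation — rather than by intron number, because published
intron numbering conventions are ambiguous (0- versus 1-anchored relative
to the exon count). Editing sites are counted in each flank per sample with
half-open interval logic (a site exactly at an intron end coordinate is
outside). Alu pairs across the two flanks are classified by the strand
combination of the genomically left and right element: convergent (+/−),
divergent (−/+) or same-orientation; convergent plus divergent are the
inverted, circularisation-competent pairs. Because these classes are
symmetric under strand exchange, counting in genomic orientation gives the
same totals as counting relative to the host strand.

## Sanger-clone quantification

Clone sequences are aligned to a supplied reference region by affine-gap
local alignment (match +1, mismatch −1, gap open −2, gap extend −1), trying
both orientations. Identity is computed as matching columns over the clone
length, so a clone whose best local hit covers only a fragment is rejected
(< 70%) even if the fragment matches perfectly — with pure
aligned-column identity a scrambled clone would always pass via some short
perfect match. The editing percentage is 100 × (reference adenosines read
as G) / (reference adenosines in the aligned span); gaps at adenosine
columns leave the denominator, and non-A>G mismatches are reported
separately but never counted as editing.

## The synthetic-data generator

Because the study's sequencing data are not publicly deposited, every stage
is exercised on synthetic data with planted ground truth. The generator
builds a miniature genome of multi-exon genes (UTR flanks, exons and introns
with canonical GT..AG splice dinucleotides on the sense strand), embeds
Alu-like elements — copies of a fixed adenosine-rich 300-nt synthetic
consensus, 5% diverged per copy and reverse-complemented for minus-strand
placements — in chosen introns, and plants:

* editing sites at sense-strand adenosines of each Alu, with per-site
  control rates drawn from `editing_rate_range` (default 0.1–0.5, the
  realistic span of per-site A-to-I ratios, which includes sites near the
  caller's detection floor) and HF rates multiplied by
  `hf_editing_multiplier` (default 0.5 — a halving, encoding the direction
  of the editing loss without asserting an unprinted effect size);
* heterozygous A>G SNPs at remaining Alu adenosines — the hardest
  confounder for an editing caller — some written to the known-variant VCF
  and some left only for the matched-DNA check;
* back-splice junctions at annotated exon boundaries with per-group read
  support (default 5 control / 20 HF reads per sample, a 4× increase).

RNA reads are drawn uniformly over each gene's contiguous pre-mRNA
(total-RNA libraries retain intronic coverage, and contiguous pre-mRNA
avoids spliced CIGARs that would add nothing testable), carry the planted
alleles at their per-group rates, SNPs at 0.5, and independent sequencing
errors (default 0.1%). Back-splice reads spanning the head-to-tail joint go
only to the unmapped FASTQ. DNA reads cover the whole genome uniformly and
carry SNPs but never editing. Every output is deterministic under the seed,
and a JSON truth manifest records all planted features.

Default problem sizes — two genes of five exons, a ~10-kb genome, 50×
RNA coverage, four samples per group — are deliberately small: they give
every per-site binomial check hundreds of observations while keeping a full
pipeline run in seconds. Caller-validation runs use
`editing_rate_range = c(0.4, 0.8)` so that planted per-group ratios stay at
or above 0.2, the regime in which exact set-recovery is a meaningful
expectation; the default range instead spans the detection floor, which is
what lets a halving of editing rates show up as a drop in per-sample
detected-event counts, as it would in real data.

What the generator does not emulate — quality-score error models, GC and
fragment-length bias, stranded-library artefacts, hyper-edited read
clusters, alignment ambiguity of real Alu copies against a full genome —
bounds what green tests can claim: they demonstrate correctness of the
logic (coordinates, filters, exclusions, statistics), not performance on
patient data.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at the GTF/VCF boundary. One convention prevents off-by-one drift.
* Overlapping genes resolve segment labels with precedence
  exon > UTR > intron; repeat context resolves alu > other repeat, ties by
  smallest element start.
* A zero-coverage Alu profile returns an empty table with a warning; a
  zero-adenosine clone span returns NA with a warning; a zero control mean
  yields an infinite fold-change sentinel; constant vectors make
  correlation undefined and are flagged rather than computed.
* All-identical group values short-circuit the test gate with p = 1 rather
  than feeding a degenerate Shapiro–Wilk.
* Probes near contig ends are truncated symmetrically and flagged.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates all synthetic
inputs from the seed, runs the full pipeline, and writes the recovered
quantities (sensitivity, precision, A-to-I fraction, junction recovery,
fold change, calibration, clone percentages) as JSON. The testthat suite
asserts the same properties at fixed seeds, including brute-force oracle
equivalence for the interval classifiers and permutation calibration of the
group tests.
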