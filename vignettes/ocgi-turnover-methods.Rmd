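---
title: "Methods: comparative turnover analysis of orphan CpG islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative turnover analysis of orphan CpG islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocgiturnover)
```

## The problem

CpG islands outside of annotated promoters and exons — orphan CpG islands
(oCGIs) — are candidate regulatory elements. Comparing them across species
asks three linked questions: where are oCGIs gained and lost (turnover);
whether oCGI turnover travels with the turnover of enhancer-associated
histone-modification peaks; and whether species-specific oCGIs sitting in
species-specific peaks are accompanied by expression changes in nearby
genes. This package implements that comparative pipeline — CpG island
calling, orphan filtering, cross-species orthology, and the null models
used to test each association — together with seeded synthetic-data
generators that plant known ground truth, so every statistical stage has a
parameter-recovery test.

## Coordinates and interval algebra

All coordinates are 0-based half-open, in memory and in every BED file
read or written; conversion to the 1-based closed convention happens only
internally at the IRanges boundary. Merging fuses book-ended intervals
(distance 0), matching the default behavior of `bedtools merge`, and can
carry a comma-collapsed list of constituent names (the `-c 4 -o collapse`
idiom used to preserve the species of origin when interval sets from
several species are merged on a common reference).

Promoter windows are derived strand-aware: for a `+` gene with TSS at p
the window is `[p - w, p)`, for a `-` gene `[p, p + w)` with `w` = 2 kb by
default. "Upstream" is meaningless without strand, so TSS feature sets
must carry it; windows are clipped at contig ends (the behavior at contig
ends is not otherwise constrained, and clipping is the conservative
choice).

## The CpG island caller

The caller uses the canonical thresholds: length >= 200 bp, GC fraction
>= 0.5, and observed/expected CpG ratio >= 0.6, with the expected CpG
count in the Gardiner-Garden–Frommer form `#C * #G / L`. Statistics are
computed over the uppercase-normalized subsequence; N bases (including
normalized soft-masked bases) are excluded from the base counts while `L`
remains the full interval length.

The segmentation is a left-to-right windowing scan over CpG positions. A
candidate is anchored at a CpG and extended one downstream CpG at a time;
the candidate interval spans from the first CpG's C to the last CpG's G.
When the span first reaches 200 bp the GC and O/E criteria are tested: on
a pass the candidate keeps growing until the first failure (or sequence
end), at which point the last passing interval is emitted and the scan
resumes after it; on an initial failure the anchor CpG is dropped and
extension continues. Two consequences are tested as invariants: emitted
calls are disjoint, sorted and re-pass all three thresholds when
recomputed independently, and every call is locally maximal (adding the
next downstream CpG breaks a criterion).

Two reading choices deserve note. First, "the interval between two CpGs
reaching 200 bp" is read as the candidate span reaching 200 bp — the
alternative (a gap of 200 bp between consecutive CpGs) would terminate
islands rather than found them. Second, because repeat-masked genomes
drive calling, soft-masked (lowercase) bases are normalized to N before
any computation; they can neither form CpGs nor contribute to counts.
Candidates additionally never span an N run of 50 bp or more
(`mask_break_bp`): masked sequence is unavailable to the caller, and a
candidate bridging a masked block would have its length inflated by bases
excluded from the counts, producing spurious high O/E ratios on the far
side of repeats. The 50 bp default is far below the size of any masked
repeat block worth the name and far above the sporadic single-N noise of
real assemblies.

## Orphan filtering

A CGI becomes an oCGI by surviving exclusion (at 1 bp of overlap) against
every supplied feature set: exons, promoter windows derived from TSSs,
blacklist regions, and CAGE-derived promoter sets. Exclusion is
data-driven — whichever feature sets are supplied are excluded — so the
asymmetric annotation depth of well-annotated genomes is configuration
rather than code. A second, cross-species filter lifts each oCGI to the
human genome through a coordinate map and removes those that fail to map
or whose human interval overlaps human exclusion features; survivors keep
source-genome coordinates. This guards against unannotated exons and
promoters in sparsely annotated genomes.

## Coordinate maps and orthology

Coordinate maps are liftOver surrogates: equal-length aligned block pairs,
non-overlapping and order-preserving per chromosome, with indel gaps
between blocks. An interval maps when at least `min_match = 0.8` of its
bases lie in aligned blocks on a single target chromosome in collinear
order; the mapped interval runs from the image of its first mappable base
to that of its last. The 0.8 default is the standard liftOver `minMatch`
used for interval conversion; requiring a mapped *fraction* rather than
complete coverage tolerates small indels without discarding real
orthologs. Non-collinear (split) projections are treated as unmapped
rather than guessed.

Orthologous sites for a species pair are built through the human
intermediate: both species' oCGIs are lifted to human, overlapping or
book-ended projections are merged into anchors with source tracking, and
an anchor becomes a site only when it maps back to *both* species — the
underlying sequence must exist in both genomes, so that absence of a call
is genuine turnover rather than missing orthology. Sites are labeled
A-only, B-only or shared by which species contribute an oCGI. When a
species lacks a call, its O/E can be recomputed from supplied genome
sequence at the back-mapped interval; otherwise it is treated as 0 by the
minimal-O/E-difference filter (the conservative, maximal-difference
reading). That filter removes species-specific sites whose per-species
O/E values differ by less than a chosen delta, and is monotone: larger
deltas can only shrink the species-specific sets.

Gain/loss polarization with an outgroup is deliberately strict: a gain on
the focal branch requires presence in the focal species and absence in
both sister and outgroup; a loss the mirror image; everything else is
unpolarized.

## Null models

Three distinct null models are implemented, each matched to its question.

**Genomic shuffle** (oCGI x peak overlap): each round redistributes every
oCGI uniformly at random on its own chromosome, preserving length,
avoiding excluded regions (annotated features plus repeat-masked
sequence) and avoiding other placed intervals — the semantics of
`bedtools shuffle -chrom -noOverlapping`, implemented by rejection
sampling with a 10,000-attempt cap. Because real oCGI sets are filtered
through the human genome, each shuffled set is re-passed through the
cross-species filter before scoring when a map is supplied. The expected
overlap is the mean across rounds (20,000 at full scale).

**Label permutation** (the 3x3 species-specificity grid): sites with no
peak in either species are excluded; oCGI labels are held fixed and the
multiset of peak labels is permuted across sites each round, preserving
both marginals exactly. Per cell: expected count, enrichment
(observed/expected), and a p-value. The peak-centric analysis is the same
operation with the roles of the two label sets swapped (one code path).

**Matched resampling** (HGE patterns; expression ratios): the comparison
set is resampled from the background with replacement, matched per
quantile bin — of histone signal for the HGE analysis, of mean log2
expression for the TPM-ratio analysis — so each resampled set reproduces
the test set's signal or expression profile exactly, bin for bin, every
round. Ten bins (decile matching) and 10,000 rounds are the defaults;
both are arguments. Sampling is with replacement, which keeps resampling
well-defined even when a bin's background membership is small; a bin with
test members but no background members is an error advising fewer bins.

All permutation and resampling p-values are two-sided with an add-one
correction: `p = (1 + #rounds at least as extreme as observed) /
(1 + rounds)`, extremeness measured as absolute deviation from the null
center. The two-sided form reads enrichment and depletion off the same
test, with direction from the sign of observed minus expected; the
pseudo-count keeps p-values strictly positive and slightly conservative.
Multiple testing uses Benjamini–Hochberg within a caller-declared family
(the nine grid cells, the eight triple patterns, the tested gene sets);
how widely to pool is an analysis decision, so it is left to the caller
rather than hard-coded.

In the expression test, the observed median log2 TPM ratio is normalized
by *subtracting* the median of the background resampling medians in log2
space (the multiplicative alternative in linear space is equivalent up to
the same monotone transform; subtraction in log space keeps the sign
symmetry exact). Genes with zero TPM in either species are dropped rather
than pseudo-counted — a pseudocount would put an arbitrary constant into
every ratio — and the number dropped is reported. GREAT-rule regulatory
domains use the standard basal window (5 kb upstream, 1 kb downstream,
strand-aware) extended to the nearest neighboring basal domain, capped at
1 Mb measured from the basal edge (an `max_extension_bp` argument changes
the cap); basal domains are never truncated by overlapping neighbors.

## The synthetic-data generators

The generators are pure functions of a `synthetic_spec` (seed included)
and emit their planted truth as first-class outputs, so recovery tests
never re-derive truth from the data.

*Genomes.* Background sequence is drawn iid at GC 0.41 with CpGs then
depleted to 0.25 of the iid expectation via simulated deamination (C→T or
G→A at CpGs) — the genome-wide CpG depletion factor characteristic of
mammalian genomes, which is what makes CpG islands detectable at all.
Islands (default 400 bp, GC 0.6, O/E target 1.0) are built from an exact
base composition followed by local swaps steering the CpG count, landing
within ±0.05 of the target; positions are recorded. Soft-masked blocks
(500 bp, 5% of sequence) emulate repeat masking.

*Species pairs.* A "human" anchor genome is mutated into species A and B:
indels (default 0.05/kb, geometric lengths, mean 40 bp) break the
coordinate maps into blocks, and each island is degraded by CpG
deamination (90% of CpGs, pushing O/E far below 0.6 while leaving the
sequence alignable) in the species where its planted status says it is
absent. Indels avoid planted islands so the truth stays clean.

*Peaks.* Each island receives a peak species-specificity label from an
explicit coupling model: no-peak labels are assigned independently (so
excluding no-peak sites is ignorable), and among peaked sites the
probability that a species-specific oCGI's peak carries the *same*
species label is `peak_coupling` times its marginal, with the shared-oCGI
row absorbing the complement so peak marginals are preserved exactly.
This makes the planted observed/expected enrichment of the matched grid
cell equal the coupling factor in expectation, which is the quantity the
grid test estimates. Peaks are realized as intervals (island ± 300 bp) in
the species the label names; background peaks are placed on the anchor
away from islands and mapped to both species, so they are orthologous and
cannot fake turnover. Signal is log-normal, multiplied by
`signal_boost_at_ocgi` at oCGI-containing peaks, and converted to read
counts consistent with RPKM at the stated library size.

*Expression.* 2,000 genes with log-normal baselines and
negative-binomial counts (size 20) per species; genes planted in the
A-only set get a `2^effect` boost in species A, mirrored for B. The
defaults reflect bulk RNA-seq over mammalian 1:1 ortholog sets: a few
thousand testable orthologs and moderate count dispersion. At these sizes
the A-only set holds roughly 200 genes, which makes the median log2
ratio estimable to a few hundredths — the scale on which the recovery
tests operate.

*Enhancers.* Background enhancers draw oCGI triple patterns from a fixed
mammalian-like distribution (65% with no oCGI); HGEs draw the same
distribution with the human-only probability multiplied by
`hge_pattern_multiplier` and a shifted signal distribution, so signal
matching is actually exercised.

What the generators do *not* emulate: repeat families and transposon
structure, regional GC/isochore variation, gene clusters with shared
regulation, gBGC tracts, and alignment error beyond clean indels. Passing
recovery tests therefore demonstrate that the statistical machinery is
calibrated and recovers planted effects of realistic size — not that the
pipeline is robust to every artifact of real genomes.

## Problem sizes and numerical choices

The validation suite runs the caller on a 10-Mb, five-chromosome genome
with 300 planted islands; turnover recovery uses ~500 islands over 2.1
Mb; grid calibration uses 200 replicate datasets of 2,000 sites at 1,000
permutation rounds; the shuffle null uses 60 replicates at 200 rounds
plus integrity assertions over 1,000 rounds; resampling tests use 400–
1,000 rounds. These sizes give the calibration checks binomial standard
errors a few times smaller than the tolerances they enforce. The
calibration check on the nine grid cells uses a Bonferroni-adjusted
binomial band (0.05/9 per cell) so the familywise false-alarm rate of the
check itself stays near 5%.

Degenerate inputs are handled explicitly: empty oCGI sets are an error
for overlap fractions (a rate over nothing is undefined), zero grids and
empty interval sets flow through the algebra, all-zero count vectors are
rejected for TPM, O/E is defined as 0 when a sequence has no C or no G,
and quantile bins that collapse (constant signal) degrade to a single
bin.

## Limitations

The caller reproduces the stated windowing criteria, not byte-identical
output of any historical implementation; where the original's bookkeeping
is ambiguous the post-conditions above are the contract. Coordinate maps
are single-coverage and strand-preserving; inversions, duplications and
one-to-many projections are out of scope (split projections are dropped,
with a message). Polarization supports exactly three species. Peak
calling, read mapping and HGE calling are upstream of this package:
peaks, counts and HGE labels are inputs.
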