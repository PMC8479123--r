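---
title: "Methods: 4C signal processing, breakpoint calling and CTCF convergence on derivative chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

In 3q26-rearranged acute myeloid leukemia, the *EVI1* promoter can be
deregulated by a distal enhancer that a translocation relocates into its
neighbourhood. In t(3;8)(q26;q24) the donor is a *MYC* super-enhancer from
8q24, a ~150 kb cluster of enhancer modules; a forward-oriented CTCF site a
few kb upstream of the *EVI1* transcriptional start site acts as an
enhancer-docking anchor, and the CTCF motifs inside the super-enhancer are
reverse-oriented — a convergent, loop-compatible configuration on the
derivative chromosome.

`hijackscan` implements the computational stack that such a study rests on:
in-silico restriction digestion, 4C-seq read processing into per-fragment
contact profiles, signal normalisation/smoothing/export, translocation
breakpoint calling from paired and split reads, derivative-chromosome
coordinate maps, and CTCF-orientation/enhancer-module analysis. Patient
sequencing data are access-restricted, so the package ships generators for
synthetic genomes and reads whose statistical structure matches what the
analysis assumes; the generators are first-class, tested code, and their
defaults define the simulation conditions used by the test suite and the
acceptance script.

## Fragment maps

Digestion scans the forward strand for the primary recognition sequence
(default DpnII, `GATC`, cut offset 0) and cuts at `occurrence + offset`.
Both supported default enzymes are palindromic, so scanning one strand
finds every site; non-palindromic enzymes are rejected rather than handled
incorrectly. Fragments are the intervals between consecutive cuts plus the
contig ends; zero-length intervals (a cut at a contig edge, or adjacent
cuts) are suppressed. Fragment ids are consecutive in coordinate order.
Internally, interval containers are `GRanges`; all plain-number coordinate
arguments and tables are 0-based half-open (BED convention), and WIG export
converts to 1-based.

Secondary annotation (default Csp6I, `GTAC`, offset 1) marks, per fragment,
the nearest internal secondary cut from each boundary; a fragment without
one is *blind*. Whether blind fragments should be counted is not a settled
convention; they are retained here, flagged, with an `includeBlind` switch
on the end catalog, so either policy is one argument away.

## 4C read processing

A read is assigned to a viewpoint when its prefix matches the viewpoint's
reading primer within `maxMismatch` mismatches (default 0 — simulated reads
are error-free, and the parameter is exposed for real data). Clipping
removes the primer bases *before* the primary motif: trimmed reads begin
with `GATC`, which anchors the fragment-end match and mirrors standard 4C
primer design.

The toy exact mapper looks trimmed reads up in a catalog of fragment-end
k-mers. One subtlety is deliberate: a left fragment end *begins with* the
motif (fragments start at cut sites), while a right fragment end is
catalogued as the reverse complement of the last `k` fragment bases, which
carries no motif — the motif at a ligation junction is shared, contributed
once. Left-end entries are therefore queried with the first `k` bases of
the trimmed read and right-end entries with the `k` bases following the
motif. A unique hit assigns the read; zero or several hits are tallied as
unmapped/ambiguous. The study conditions use `k = 20` (16 informative bases
beyond the motif): at toy-genome scale the chance that two fragment ends
share an informative k-mer is negligible, which is what makes exact
pipeline recovery a meaningful test. For pre-aligned reads,
`assignFromAlignments()` applies the classic filter instead: a read is kept
iff its strand-aware 5' end lies within `boundaryTolerance` (default 2 bp)
of a fragment boundary.

Contact counting removes the viewpoint fragment and `exclusionRadius`
neighbours on each side (default 1; radius 0 still removes the viewpoint
fragment itself, which carries self-ligation). Every input read lands in
exactly one tally — kept, excluded, unmapped, ambiguous, unassigned — and
the bookkeeping identity is asserted in tests.

## Signal

RPM normalisation uses as denominator the reads *kept in the profile after
all filtering*, not raw sequenced reads; the choice is recorded in output
headers. It makes profiles comparable across viewpoints with different
filtering rates, and it guarantees the conservation property
`sum(rpm) = 1e6` that the tests assert.

The running mean (default window 21) operates on the fragment-ordered value
vector, not on base pairs: 4C signal is inherently per-fragment, and the
smoothing is applied at track-generation time exactly as WIG export sees
it. Windows never cross contig boundaries, and edges *shrink* (only
existing positions are averaged) so no signal is invented beyond chromosome
ends. The implementation delegates to `zoo::rollapply(partial = TRUE)`; an
independent double-loop oracle pins the semantics in the tests. WIG
(variableStep) anchors per-fragment values at `floor((start+end)/2)` of the
0-based interval since variableStep needs single positions; bedGraph keeps
the full intervals and round-trips exactly.

Binned coverage mirrors the standard ChIP/ATAC track recipe: bin counts
(default 20 bp), RPKM `count * 1e9 / (librarySize * binSize)`, then a
running mean over `smoothLength / binSize` bins (default 100/20 = 5 bins;
an even quotient is made odd by adding one bin, a non-multiple is rounded
down, both logged).

`contactDomainExtent()` summarises how far an interaction domain reaches:
the maximal run of consecutive fragments at or above a fraction of the
regional maximum, and its genomic span.

## Breakpoint calling

`findDiscordant()` classifies a pair as discordant iff the mates map to
different contigs, or to the same contig with insert above
`maxConcordantInsert` (default 1000 bp) or in a non-FR orientation. Pairs
below `minMapq` 10 are dropped and counted. These defaults correspond to
the common pair-based caller settings for short-insert libraries; all three
are arguments.

Candidates are formed per (ordered contig pair, orientation class) by
single-linkage clustering with gap <= `clusterWindow` (1000 bp) on *both*
partners, and emitted at support >= 2 with positions at the innermost read
edges. Determinism is part of the contract: candidates sort by
`(contigA, posA)` with support as tie-break, so shuffled input yields
byte-identical output.

Split-read refinement goes beyond pair-based calling and is what delivers
base-pair-exact coordinates (the `Chr.3:168.917.999-Chr.8:130.487.191`
style of report). Each junction-spanning read is anchored by a unique
k-mer (default 15) on each flank and extended base-by-base; the modal
`(posA, posB)` wins, ties toward the smallest `posA`. When the maximal
prefix and suffix matches overlap, the junction is only defined up to the
microhomology; the refiner reports the leftmost (smallest `posA`)
representative, a fixed convention rather than a guess. Human-facing
tables are 1-based (last retained base of A, first retained base of B);
internal coordinates are 0-based.

The toy translocation genome pins the four bases flanking the planted
junction so that it carries no microhomology — a clean blunt junction, as
CRISPR-engineered translocation models aim for — which makes
"base-pair-exact recovery" well-defined regardless of the random filler.

## Derivative chromosomes

A derivative is an ordered list of oriented native segments. Mapping is
pure arithmetic — `der = offset + (pos - start)` on `+` segments,
`offset + (end - 1 - pos)` on `-` segments — and the two maps are mutually
inverse on covered positions, a property tested on random positions across
`+` and `-` segments. Uncovered positions map to `NA` (a typed result, not
an error), since annotations routinely extend past a junction. Segment
orientation is always a user input: the true orientations of patient
derivatives are generally not determined by a two-partner breakpoint alone,
and silently inferring them would be worse than asking.

## CTCF convergence and docking

Convergent pairs are all (forward, reverse) site pairs in coordinate order,
optionally span-limited — deliberately the brute-force definition, checked
against an exhaustive oracle, since site sets are small. On a derivative,
sites are first mapped into derivative coordinates and orientations flip
through inverted segments.

The docking verdict composes the two: the docking configuration is
preserved iff the docking site and the promoter are covered by the same
segment, the site is untruncated, and it carries its required orientation;
convergence across the junction is established if any reverse site
contributed by the partner segment pairs with the docking site on the
derivative. "Upstream" is defined by a user-supplied promoter strand,
never inferred from gene names (*EVI1*/*MECOM* strand conventions are an
easy trap). Preservation is monotone in junction distance, which the tests
check by sliding the junction away from the promoter block.

Module quantification counts a read toward a module iff the intervals
overlap by >= 1 bp (at most once per module), the simplest reproducible
convention; differential testing is deliberately out of scope — the
bespoke content is the interval quantification, and descriptive RPKM plus
pseudocount-1 log2 fold change is reported instead of a negative-binomial
fit.

## The synthetic-data model

The 4C generator samples partner fragments with probability proportional to
`s^-alpha` (midpoint separation `s` in cis), a constant background rate in
trans, and a multiplicative enrichment for fragments looped to the
viewpoint; fragments within a self-exclusion radius (default 5 fragments)
are never sampled, emulating the uninformative zone around a real
viewpoint. No quantitative contact model is available for the patient
locus; `alpha = 1` (the classic contact-decay exponent at sub-Mb scale),
background `1e-6` and enrichment 10 are this package's chosen defaults,
fixed once, not estimates of any dataset.

The bundled study locus (`exampleFourCLocus()`) is a single 130 kb contig
standing in for the derivative: restriction sites every 200 bp, the
viewpoint near the left end, a forward CTCF docking site 2.6 kb upstream of
it, and three reverse CTCF sites at 60/80/100 kb whose loop-anchor zones
span 25 consecutive fragments (~5 kb) each. Anchor zones span multiple
fragments for a structural reason: a window-21 running mean dilutes a
single-fragment spike ~21-fold, so a realistic several-kb anchor zone is
what lets smoothed enrichment remain visible — and real loop-anchor regions
are indeed kb-scale against ~256 bp mean DpnII fragments. Reads are
error-free with constant quality: sequencing-error models, PCR duplicates
and quality realism are out of scope, so a passing pipeline-recovery test
shows coordinate bookkeeping is exact, not that the mapper tolerates noisy
data.

The translocation toy (`exampleT38Genome()`) uses two 200 kb contigs with
origins 168,800,000 and 130,400,000, so the patient-style junction
coordinates (Chr.3:168,917,999 / Chr.8:130,487,191) are genuine inputs
rather than rescaled stand-ins. Capture simulation emits FR pairs with
Gaussian insert (500 +/- 50 bp): a chosen fraction of fragments straddle
the junction with both mates clear of it (discordant evidence), each also
yielding one read crossing the junction base with >= 15 bp on each side
(split evidence).

## Problem sizes and determinism

The test suite and acceptance script use 10,000 reads for exact pipeline
recovery, 50,000 reads for decay-slope regression (recovered exponent
within +/- 0.15) and loop enrichment (smoothed RPM at anchor centres >= 3x
the median of distance-matched non-anchor fragments), 400 capture pairs
(80 junction-spanning) for breakpoint calling, 100 random 10 kb sequences
for the digestion oracle, 100 random vectors for the smoothing oracle, and
1000 random positions for coordinate round-trips — sizes at which every
stochastic check is comfortably stable across seeds. All randomness flows
through explicit seeds with saved-and-restored RNG state; identical seed
and configuration give byte-identical FASTQ/SAM output.

## Known limitations

* The mapper is an exact-match toy for self-containment; it does not
  replace a gapped aligner on real reads.
* The breakpoint caller handles two-partner junctions (translocations and
  simple inversions); no CNV, insertion or complex-event support.
* Split-read refinement assumes spanning reads run A-to-B in derivative
  orientation; other configurations fall back to interval resolution.
* Contact simulation is per-fragment multinomial; it does not model
  circularisation bias, undigested runs, or PCR duplicates.
* Docking verdicts are structural (coverage, truncation, orientation,
  convergence); they say nothing about occupancy or activity.
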