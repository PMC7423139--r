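---
title: "Detecting regional expansion and collapse in heterozygous assemblies"
author: "hetscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regional expansion and collapse in heterozygous assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscope)
```

## The signature model

A diploid sample at around 1% heterozygosity presents a de novo
assembler with a dilemma at every heterozygous locus: merge the two
alleles into one consensus, or keep them apart. In a de Bruijn graph
the alleles form bubbles, and N nearby heterozygous sites can induce up
to 2^N partial paths. When the paths are emitted as contigs, the region
is *expanded*: its sequence is present twice (or more), reads split
between the copies, and — because each read now maps to its own allelic
copy — the variant caller sees almost no heterozygous sites there.
Conversely, when near-identical repeat copies *collapse* into one
sequence, reads from every copy pile onto the survivor and inter-copy
divergence masquerades as heterozygosity.

That gives each artifact a three-dimensional signature relative to a
trusted reference, measured per region:

| signature | length ratio | coverage ratio | heterozygosity ratio |
|-----------|--------------|----------------|----------------------|
| expansion (factor 2) | 2 | 1/2 | → 0 |
| collapse (factor k)  | 1/k | k | elevated |
| correct | 1 | 1 | 1 |

The ratios are deliberately redundant: length and coverage must move in
opposite directions for a pure artifact, which `classifyRegion()`
exploits. A region set showing inflated length *and* inflated
heterozygosity cannot be a pure artifact and is labelled `mixed`
(expansion and collapse superimposed in one functional category);
anything else inconsistent is `unresolved` rather than forced into a
class.

## The regional pipeline and its thresholds

`regionSetAnalysis()` mirrors the classic transcript-anchored workflow:

1. **Locate genes on the test assembly** from transcript-vs-assembly
   alignments. Exon-level hits at `>= 92%` identity (strict boundary:
   91.9 is out) are grouped per (transcript, contig) and the region is
   the min..max of the kept coordinates. Regions spanning more than
   10 kb are excluded as probable mapping errors. The 92% floor admits
   allelic copies of a 1%-heterozygosity genome with margin but rejects
   most cross-gene noise; both values are configurable.
2. **Measure each region** on the test assembly: SNP sites per bp from
   the assembly's own VCF, mean per-base depth with absent positions
   counted as zero.
3. **Match regions onto the reference** at `>= 98%` identity. This
   threshold is doing real work: it must admit the true allelic
   counterpart (identity ≈ 100 − heterozygosity% ≈ 98.85) while
   rejecting paralogous regions; relaxing it changes the denominator
   of every ratio, which is why the length comparison exposes the
   identity floor as a parameter.
4. **Pool per region set and divide.** Counts are pooled before
   dividing (length-weighted), not averaged per gene — tiny regions
   would otherwise dominate the mean. Reference bases are counted once
   by merging overlapping HSPs, so an expanded gene contributes twice
   to the numerator but once to the denominator; that asymmetry *is*
   the length signal.

A design point worth stating: a transcript whose qualifying hits land
on two contigs is not discarded. On an allelically expanded assembly
this is the *expected* behaviour of every expanded gene — the two
haplotype contigs both attract the transcript — so discarding such
genes would blind the method to exactly the artifact it exists to
detect. Instead each (transcript, contig) pair yields its own region,
and the count of multi-contig genes is reported separately (on a
fragmented assembly it is itself a fragmentation signal).

Classification thresholds default to 1.5 / 0.67: symmetric on the fold
scale, far enough from 1 that Poisson depth noise on a ≥ 10 kb region
(relative SE below 2% at 60×) cannot cross them, and far enough from
the pure-artifact values (2, 0.5, 1/k) to tolerate partial artifacts.

## The fragmentation/duplication classifier

Predicted proteins from a test assembly are compared against reference
proteins in an all-vs-all table. Per reference protein, match intervals
on the protein are single-linkage clustered by overlap (any shared
position; a minimum-overlap fraction is available as a knob). With N
matches in C clusters the protein contributes N − C duplication events,
a fragmentation case if C > 1, and a 1:1 match if N = 1. The two pure
cases reduce to the familiar counting: K mutually overlapping matches
are K − 1 duplicates plus one correct match (conservative by
construction — never K), and non-overlapping matches are fragmentation
with zero duplications. Reference proteins with any non-self reference
match are excluded *symmetrically* (both endpoints): a paralogous
family would otherwise be misread as assembly duplication, and
excluding only the query side would leave the partner conflatable.
Per-protein raw (N, C) counts are returned so either the "cases" or
the "events" convention is recoverable.

## What the synthetic generator emulates — and what it does not

`generateDiploid()` draws a uniform-composition background at 40% GC
(typical for a nematode genome), embeds tandem repeat families (each
copy independently diverged from the family consensus at 0.5% per
base), and creates haplotype B by substituting at sites sampled at
1.15% per bp — the study conditions for a highly heterozygous
invertebrate at 60× coverage with 200/1000 bp length cutoffs. The
repeat divergence default sits deliberately *above* the SNP rate's
contribution yet *inside* the 98%-identity matching window, so
collapsed copies remain comparable to all their reference copies while
still inflating apparent heterozygosity.

`makeTestAssembly()` injects artifacts with exact bookkeeping: an
expansion replaces its region with both haplotype copies as separate
contigs (length gain = region length); a collapse replaces k adjacent
repeat copies with their per-column majority consensus (loss =
(k−1) × unit); a bubble artifact emits up to 2^n allelic path contigs
(capped at 2^10 to bound pathological blow-up).

`simulateMappingProfile()` draws the depth/SNP consequences directly
from the artifact model — Poisson depth at the expected rate per
segment role, heterozygous calls present, suppressed or
divergence-driven as the role dictates — rather than simulating reads.
This is a deliberate shortcut: the claims under test concern the
signatures, not mapper behaviour, and it keeps a full 1 Mb end-to-end
run in seconds. The price is that several properties of real data are
*not* emulated: sequencing error, mapping-quality artifacts, indels
(the simulator is substitution-only, so coordinates project 1:1),
GC-coverage bias, partial allele-aware mismapping (exposed as
`mismapRate`, default 0 — the idealized limit), and assembler-specific
contig-boundary placement. Passing tests therefore demonstrate that
the *measurement and classification logic* recovers known truth under
the stated noise model; they do not certify performance on real reads.

## Numerical choices and degenerate inputs

- Intervals are 1-based closed throughout (the IRanges convention);
  tabular inputs (alignment, VCF, depth) are already 1-based inclusive,
  so no coordinate conversion is ever applied.
- Depth positions absent from a file read as 0 (`samtools depth`
  omits zero rows by default); whether the original pipelines included
  zero rows is unknowable from the outputs, and zero-fill is the
  conservative reading.
- A multiallelic SNP site counts once: heterozygosity is defined per
  segregating site, not per allele. Indels and symbolic alleles are
  dropped.
- N50 uses the descending cumulative scan with `>=` at the half-total,
  returning a member of the input; the exhaustive small-case oracle in
  the tests pins the tie behaviour.
- Length cutoffs are inclusive (`>= cutoff` kept).
- Zero reference denominators (no matched reference bp, or zero
  reference heterozygosity) leave the affected ratio `NA` and the set
  flagged `unresolved` — never silently 0 or Inf. An assembly shorter
  than the recovered reference reports zero expansion with a
  `net_deficit` flag rather than a negative percentage.
- Alignment rows with reversed subject coordinates are flipped once at
  read time and flagged; re-normalizing is a no-op.

## Problem sizes used in the test suite

The suite exercises the full parameter-recovery loop on a 1 Mb genome
(the scale at which a ≥ 10 kb region's depth estimate is tight) and
runs the 100-replicate classification-accuracy study at 80 kb per
replicate — ample for 10 kb artifact regions while keeping the whole
suite under two minutes. These sizes are the package's own validation
design; the machinery is linear in genome length and has been run at
multiples of these sizes.

## Known limitations

- The expansion model emits exactly two allelic copies (or 2^n bubble
  paths); real assemblies can emit partially redundant path fragments
  that are neither full copies nor clean paths.
- Region matching trusts the supplied alignment tables; systematically
  missing alignments (e.g. a repeat-masked aligner run) would surface
  as `unresolved` sets rather than misclassifications.
- The fragmentation/duplication classifier counts events relative to
  reference proteins only; novel genes absent from the reference are
  invisible to it.
- Classification of *mixed* sets is qualitative: the two superimposed
  artifacts cannot be deconvolved from three pooled ratios alone, and
  the per-region metrics table is provided for finer dissection.

## Session-free demo

```{r demo, eval = FALSE}
b <- syntheticBenchmark(genomeLength = 8e4, seed = 1)
b$ratios[, c("region_set_id", "het_ratio", "cov_ratio", "len_ratio",
             "classification")]
```
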