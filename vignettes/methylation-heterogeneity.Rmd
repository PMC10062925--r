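---
title: "Measuring within-sample DNA methylation heterogeneity in one sweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring within-sample DNA methylation heterogeneity in one sweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsweep)
```

## The problem

Bulk bisulfite sequencing averages methylation over thousands of cells, but
each *read* is a snapshot of a single molecule: the phased vector of binary
CpG states along one read — its **epiallele** — acts as a pseudo-barcode for
the cell it came from. A locus can be 50% methylated because every cell is
hemi-methylated, or because half the cells are fully methylated; average
methylation cannot tell these apart, while within-sample heterogeneity
measures can. `methsweep` computes the seven established measures from
coordinate-sorted SAM/BAM alignments whose reads carry Bismark-style
per-base methylation call strings (the `XM` tag).

## The measures

Let a read's calls be the ordered binary states of the CpGs it covers.

* **PDR** (proportion of discordant reads), per CpG: the fraction of
  classified covering reads containing both a methylated and an
  unmethylated call. A read is classified only if it carries at least
  `min_cpgs` calls (default 4, following the original definition).
* **LPMD** (local pairwise methylation discordance): the fraction of
  same-read CpG pairs at genomic distances within `[d_min, d_max]` bp
  (default 2–16, measured between the forward-strand C coordinates) whose
  states differ. Because pairs are conditioned on distance rather than on
  whole reads, LPMD is comparable across experiments with different read
  lengths — the design reason for the measure, which this package's
  acceptance suite reproduces (PDR drifts with 3'-trimmed read length,
  LPMD does not).
* **MHL** (methylation haplotype load), per CpG: with `P(MH_i)` the
  fraction of contiguous length-`i` substrings, pooled over the full call
  vectors of all covering reads, that are fully methylated,
  `MHL = sum(i * P(MH_i)) / sum(i)`. Substring lengths with no occurrences
  are excluded from both sums (they carry no evidence, and treating them as
  zero would penalize shallow loci).
* **PM** (epipolymorphism) and **ME** (methylation entropy), per CpG
  quartet: with `p` the frequency vector of the 16 patterns over 4
  consecutive CpG calls, `PM = 1 - sum(p^2)` (range 0–15/16) and
  `ME = -(1/4) sum(p * log2 p)` (range 0–1, `0·log 0 = 0`).
* **FDRP** and **qFDRP**, per CpG: over pairs of covering reads, the
  fraction of pairs disagreeing at ≥ 1 shared CpG, and the mean normalized
  Hamming distance `hamming/shared`. Pairs sharing no position are excluded
  from the denominator (discordance is undefined without shared positions);
  `qFDRP <= FDRP` always, since `hamming/shared <= 1{hamming > 0}`.

## The one-sweep design

All measures are accumulated read-centrically: the sorted stream is walked
once, each read updates the accumulators of every CpG, pair or quartet it
touches, and nothing is ever re-fetched. A CpG-centric alternative re-reads
every alignment once per CpG it covers, costing λ·n read accesses where λ is
the mean number of CpG calls per read (`cpgs_per_read_stat()`); in
CpG-enriched RRBS data λ is substantially above 1, which is where the
one-sweep design wins. Correctness of the sweep is checked in the test suite
against an independent, deliberately naive CpG-centric recomputation, with
exact equality required.

FDRP/qFDRP are quadratic in depth if done exhaustively, so each CpG keeps a
uniform **reservoir** (Algorithm R) of at most `capacity` covering reads
(default 40, matching the read cap of the reference R implementation). One
seeded RNG drives all reservoirs in sweep order, so a fixed
`(input, flags, seed)` triple gives byte-identical output; with
`capacity >= depth` no random draw ever happens and the result is exactly
the exhaustive one.

## Input conventions

* Coordinates are 0-based half-open in all outputs (BED-like TSV:
  `chrom start end value depth`); a per-CpG record spans the CpG
  dinucleotide (`end = start + 2`).
* `Z`/`z` in the call string are methylated/unmethylated CpG calls; all
  other characters (CHG/CHH/unknown context) are dropped, never imputed.
* A reverse-strand read's call sits on the G of the CpG; the parser shifts
  it by −1 so both strands collapse onto the forward-strand C and all
  accumulators are strand-agnostic (CpG methylation is symmetric).
* Input must be coordinate-sorted (validated by a monotonicity check): the
  sweep's bounded memory comes from flushing loci the sweep has passed.
* Overlapping mates of a paired-end fragment are treated as independent
  reads; the upstream convention on mate deduplication is not specified, so
  the package takes the simpler and configurable position.
* Default filters: mapping quality ≥ 10; secondary, supplementary,
  duplicate, unmapped and QC-fail reads are skipped. These are ordinary
  bisulfite QC defaults, all exposed as flags.

Alignments from non-Bismark aligners lack `XM`; `tag_alignments()` derives
it from a reference FASTA, calling only CpG context (read C→`Z`, T→`z` on
the forward strand; mirrored onto the G for reverse-strand reads) and
emitting `.` elsewhere, including CHG/CHH.

## The simulator as a stated world

`simulate_alignments()` generates RRBS-like alignments with known truth:
each locus has k CpGs and an explicit epiallele distribution over the 2^k
patterns; every read draws one pattern i.i.d., starts at the locus's first
CpG minus a uniform 0–5 bp offset (mimicking restriction-site anchoring and
producing the deep pile-ups that exercise the flush logic), and is written
as valid tagged, sorted SAM. `analytic_measures()` computes every measure's
expectation by exhaustive enumeration over patterns and pattern pairs — an
implementation path disjoint from the streaming code, so recovery tests are
genuine cross-checks.

What the simulator does *not* emulate: sequencing base errors (the
`call_error` parameter flips stored calls instead, which suffices to test
robustness of the accumulators but not of base calling), fragment-length
variation, paired-end mates, incomplete bisulfite conversion, and real CpG
spacing distributions. A green recovery test therefore establishes that the
accumulators implement their definitions, not that any particular biology
holds.

The read-length experiment uses a stated world fixed before any test was
run: 200 loci of 13 CpGs spaced 4 bp (span 48 bp within 50 bp reads), depth
50, and an epiallele process of a 50/50 fully-methylated/fully-unmethylated
base pattern with independent 5% per-CpG flips. The flips are i.i.d. per
CpG, so pairwise discordance at any fixed distance is length-independent
(LPMD stable by construction) while the chance a read contains at least one
flipped CpG grows with the number of CpGs it covers (PDR grows with read
length). Trimming (`trim_calls_3prime()`) removes the 3' end in read
orientation — the reference-right end of forward reads, the reference-left
end of reverse reads (whose `pos` advances) — and can only remove calls,
never add them.

## Numerical and design choices

* Depth thresholds default to 10 (per-CpG and per-quartet measures) — the
  upstream work is silent here, and 10 is common heterogeneity-calling
  practice; LPMD's per-pair output uses a per-pair minimum of 4 while the
  pooled global value uses every pair.
* Quartet identity is the exact observed 4-coordinate tuple: reads whose 4
  consecutive calls skip a genomic CpG form a different quartet. This keeps
  the sweep free of any genome-wide CpG catalog dependency.
* Per-CpG MHL uses the full call vector of every covering read, not a
  window around the CpG; FDRP/qFDRP likewise compare the full read overlap.
* Ties in output ordering are broken by (chrom in header order, start,
  end, then quartet coordinates), making outputs deterministic.
* Entropy uses log base 2 and the `0·log 0 = 0` convention; degenerate
  inputs (zero-depth quartets, empty haplotype sets) are errors for the
  low-level functions and filtered upstream by the sweep.
* An empty stream is not an error: measures return zero records, the
  global LPMD and λ are reported missing.

## Limitations

* The engine is pure R over an in-memory parsed stream; the algorithmic
  contract (each record touched once, position-local accumulation) is kept,
  but constant factors are R-sized. The original motivation — beating
  CpG-centric tools by orders of magnitude of wall clock — is about
  algorithm shape, which is preserved; raw speed benchmarking is out of
  scope here.
* No genomic-context annotation (islands/shores/repeats): intersect the
  BED-like outputs with annotation tracks downstream.
* `tag_alignments()` calls CpG context only; CHG/CHH calling and duplicate
  marking are out of scope.
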