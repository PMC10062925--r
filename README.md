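# methsweep

One-pass computation of within-sample DNA methylation heterogeneity from
bisulfite read alignments.

## What problem this solves, and for whom

Bulk bisulfite sequencing reports an average methylation level per CpG, but
every *read* is a single-molecule snapshot: the phased vector of binary CpG
states along a read (its **epiallele**) distinguishes a population of
hemi-methylated cells from a 50/50 mix of fully methylated and fully
unmethylated cells, which identical averages cannot. `methsweep` is for
epigenomics researchers who have coordinate-sorted SAM/BAM alignments with
Bismark-style per-base methylation call strings (the `XM` tag) and want the
seven established within-sample heterogeneity measures, computed
read-centrically in a single sweep over the file:

| measure | unit | quantifies |
|---|---|---|
| PDR | per CpG | fraction of covering reads carrying both methylated and unmethylated calls |
| LPMD | global / per pair / per distance | fraction of same-read CpG pairs at 2–16 bp distance whose states differ |
| MHL | per CpG | length-weighted conservation of fully methylated haplotype stretches |
| PM (epipolymorphism) | per CpG quartet | `1 − Σ p_i²` over the 16 four-CpG pattern frequencies |
| ME (methylation entropy) | per CpG quartet | `−(1/4) Σ p_i log₂ p_i` |
| FDRP | per CpG | fraction of covering-read pairs disagreeing at ≥ 1 shared CpG |
| qFDRP | per CpG | mean normalized Hamming distance over shared CpGs |

FDRP/qFDRP bound their quadratic per-CpG cost with uniform reservoir
sampling (capacity 40 by default; exact and deterministic whenever capacity
≥ depth). LPMD conditions on a fixed pair-distance window, making it
comparable across read lengths where PDR is not — the test suite reproduces
exactly this contrast on 3'-trimmed simulated reads.

Also included: `tag_alignments()` to derive `XM` strings from a reference
FASTA for non-Bismark aligners, a ground-truthed RRBS-like simulator with
closed-form expectations for every measure, a 3' trimmer for read-length
experiments, and a subcommand CLI (`exec/methsweep`). All outputs are
0-based half-open BED-like TSV (`chrom start end value depth`).

## Worked example

Two 4-CpG loci at depth 60: one with uniform epialleles over all 16
patterns (maximal quartet diversity), one a 50/50 mix of fully methylated
and fully unmethylated molecules (bimodal, locally homogeneous).

```r
library(methsweep)
cfg <- list(
  locus_config("chr1", c(100L, 104L, 108L, 112L), rep(1/16, 16), depth = 60L),
  locus_config("chr1", c(500L, 503L, 506L, 509L),
               c(0.5, numeric(14), 0.5), depth = 60L))
sim <- simulate_alignments(cfg, seed = 42, sam_path = "example.sam")

reads <- stream_methyl_reads("example.sam")
cpgs_per_read_stat(reads)$lambda
#> [1] 4

compute_pdr(reads, min_depth = 10)
#>     chrom start   end     value depth
#> 1:   chr1   100   102 0.7666667    60
#> ...
#> 5:   chr1   500   502 0.0000000    60
```

At the uniform locus most reads mix states (PDR 0.77, analytic expectation
0.875 ± sampling noise at depth 60); at the bimodal locus every read is
internally homogeneous, so PDR is exactly 0 even though the population is
maximally bimodal — which FDRP-style pair measures do detect:

```r
compute_pm_me(reads, min_depth = 10)$pm
#>     chrom start   end     value depth
#> 1:   chr1   100   114 0.9233333    60   # near the 0.9375 uniform maximum
#> 2:   chr1   500   511 0.4727778    60   # near the 0.5 two-pattern value

compute_lpmd(reads)$global
#> [1] 0.2180851

sim$truth[, .(locus, pdr, pm, me, mhl, lpmd, fdrp, qfdrp)]
#>    locus   pdr     pm    me    mhl  lpmd   fdrp qfdrp
#> 1:     1 0.875 0.9375  1.00 0.1625   0.5 0.9375   0.5
#> 2:     2 0.000 0.5000  0.25 0.5000   0.0 0.5000   0.5

write_records(compute_pdr(reads, min_depth = 10), "example.pdr.bed")
#> chr1	100	102	0.766667	60
```

`sim$truth` holds the analytic expectation of every measure under each
locus's epiallele distribution, computed by exhaustive enumeration — an
independent path the streaming results are tested against.

The same pipeline from the shell:

```sh
exec/methsweep pdr   --input example.sam --output example.pdr.bed --min-depth 10
exec/methsweep lpmd  --input example.sam --output example.lpmd.bed \
                     --output-distance example.lpmd.dist.tsv
exec/methsweep fdrp  --input example.sam --output example.fdrp.bed --seed 7
```

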