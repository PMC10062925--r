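Package: methsweep
Title: One-Pass DNA Methylation Heterogeneity Measures from Bisulfite
    Alignments
Version: 0.1.0
Authors@R:
    person("Dana", "Kim", email = "dana.kim@example.org",
           role = c("aut", "cre"))
Description: Computes seven within-sample DNA methylation heterogeneity
    measures from coordinate-sorted bisulfite read alignments that carry
    Bismark-style per-base methylation call strings (the XM tag): proportion
    of discordant reads (PDR), local pairwise methylation discordance (LPMD),
    methylation haplotype load (MHL), epipolymorphism (PM), methylation
    entropy (ME), and the fraction of discordant read pairs in plain (FDRP)
    and quantitative (qFDRP) form.  All measures are computed read-centrically
    in a single sweep over the sorted alignments; FDRP and qFDRP bound their
    per-CpG work with reservoir sampling.  Also provides a tagger that adds
    call strings to alignments from non-Bismark aligners, a ground-truthed
    RRBS-like read simulator, a 3'-trimming utility for read-length
    experiments, and a subcommand-style command line interface.  Outputs are
    BED-like 0-based half-open intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    jsonlite,
    optparse,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
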