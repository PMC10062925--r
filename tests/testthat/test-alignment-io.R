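write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           targets = c(chr1 = 10000L)) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(targets),
                       as.integer(targets)),
               records), path)
  path
}

sam_line <- function(qname, flag, chrom, pos1, mapq, cigar, seq, xm = NULL) {
  ln <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                qname, flag, chrom, pos1, mapq, cigar, seq,
                strrep("I", nchar(seq)))
  if (!is.null(xm)) ln <- paste0(ln, "\tXM:Z:", xm)
  ln
}

test_that("parse_methylation_calls maps XM characters through the CIGAR", {
  r <- list(qname = "f", flag = 0L, chrom = "chr1", pos = 100L, mapq = 42L,
            cigar = "9M", call_string = "..Z..H..z")
  mr <- parse_methylation_calls(r)
  expect_identical(mr$pos, c(102L, 108L))
  expect_identical(mr$meth, c(TRUE, FALSE))

  # reverse-strand call sits on the G; coordinate collapses to the C
  rv <- list(qname = "r", flag = 16L, chrom = "chr1", pos = 200L, mapq = 42L,
             cigar = "5M", call_string = "..Z..")
  expect_identical(parse_methylation_calls(rv)$pos, 201L)

  # no CpG-context characters at all -> SKIP
  nc <- list(qname = "n", flag = 0L, chrom = "chr1", pos = 10L, mapq = 42L,
             cigar = "6M", call_string = "..xH..")
  expect_null(parse_methylation_calls(nc))
})

test_that("parse handles soft clips, deletions and insertions", {
  # 2S 3M 1D 2M 1I 2M: query offsets 3..5 -> 100..102, D skips 103,
  # 6..7 -> 104..105, offset 8 is inserted (no call), 9..10 -> 106..107
  r <- list(qname = "x", flag = 0L, chrom = "chr1", pos = 100L, mapq = 42L,
            cigar = "2S3M1D2M1I2M", call_string = "..Z...zZ.z")
  mr <- parse_methylation_calls(r)
  expect_identical(mr$pos, c(100L, 105L, 107L))
  expect_identical(mr$meth, c(TRUE, FALSE, FALSE))
})

test_that("parse skips filtered reads and enforces contracts", {
  base <- list(qname = "q", chrom = "chr1", pos = 5L, mapq = 42L,
               cigar = "3M", call_string = "Z..")
  for (fl in c(4L, 256L, 512L, 1024L, 2048L))
    expect_null(parse_methylation_calls(c(base, flag = fl)))
  expect_null(parse_methylation_calls(c(base[-4], mapq = 3L, flag = 0L)))
  bad <- c(base[-6], call_string = "Z.", flag = 0L)
  expect_error(parse_methylation_calls(bad), "length")
  untagged <- c(base[-6], flag = 0L)
  expect_error(parse_methylation_calls(untagged), "tag")
})

test_that("stream_methyl_reads filters flags and keeps file order", {
  lines <- c(
    sam_line("a", 0L, "chr1", 101L, 42L, "4M", "CGAA", "Z..."),
    sam_line("b", 256L, "chr1", 101L, 42L, "4M", "CGAA", "Z..."),  # secondary
    sam_line("c", 1024L, "chr1", 101L, 42L, "4M", "CGAA", "Z..."), # duplicate
    sam_line("d", 0L, "chr1", 150L, 42L, "4M", "TGAA", "z..."),
    sam_line("e", 0L, "chr1", 200L, 42L, "4M", "CGAA", "Z..."))
  reads <- stream_methyl_reads(write_test_sam(lines))
  expect_identical(reads$n_records, 5L)
  expect_identical(length(reads), 3L)
  expect_identical(reads$qname, c("a", "d", "e"))
  expect_identical(reads$start, c(100L, 149L, 199L))
})

test_that("unsorted input and missing tags are hard errors", {
  unsorted <- c(sam_line("a", 0L, "chr1", 500L, 42L, "4M", "CGAA", "Z..."),
                sam_line("b", 0L, "chr1", 100L, 42L, "4M", "CGAA", "Z..."))
  expect_error(stream_methyl_reads(write_test_sam(unsorted)), "sort")

  # chr2 record before chr1 block violates header contig order
  cross <- c(sam_line("a", 0L, "chr2", 100L, 42L, "4M", "CGAA", "Z..."),
             sam_line("b", 0L, "chr1", 100L, 42L, "4M", "CGAA", "Z..."))
  expect_error(
    stream_methyl_reads(write_test_sam(
      cross, targets = c(chr1 = 10000L, chr2 = 10000L))),
    "sort")

  untagged <- sam_line("a", 0L, "chr1", 100L, 42L, "4M", "CGAA")
  expect_error(stream_methyl_reads(write_test_sam(untagged)), "tag")
})

test_that("strand collapse puts both orientations on the same coordinate", {
  lines <- c(sam_line("f", 0L, "chr1", 101L, 42L, "4M", "CGAA", "Z..."),
             sam_line("r", 16L, "chr1", 101L, 42L, "4M", "CGAA", ".Z.."))
  reads <- stream_methyl_reads(write_test_sam(lines))
  expect_identical(reads$pos[[1L]], reads$pos[[2L]])
})

test_that("cpgs_per_read_stat returns the mean and histogram", {
  reads <- structure(list(pos = list(1:2, 1:4, 1:6),
                          chrom = rep("chr1", 3)), class = "methyl_reads")
  st <- cpgs_per_read_stat(reads)
  expect_identical(st$lambda, 4)
  expect_identical(as.integer(st$histogram), c(1L, 1L, 1L))
  empty <- structure(list(pos = list(), chrom = character(0)),
                     class = "methyl_reads")
  expect_true(is.na(cpgs_per_read_stat(empty)$lambda))
})

test_that("write_records formats BED-like output and rejects unsorted input", {
  rec <- data.table::data.table(chrom = "chr1", start = 102L, end = 104L,
                                value = 0.25, depth = 12L)
  p <- tempfile()
  write_records(rec, p)
  expect_identical(readLines(p), "chr1\t102\t104\t0.250000\t12")

  write_records(rec[0L], p)
  expect_identical(readLines(p), character(0))

  bad <- data.table::data.table(chrom = "chr1", start = c(200L, 100L),
                                end = c(202L, 102L), value = c(0, 0),
                                depth = c(1L, 1L))
  expect_error(write_records(bad, p), "sorted")
  interleaved <- data.table::data.table(
    chrom = c("chr1", "chr2", "chr1"), start = c(1L, 1L, 5L),
    end = c(3L, 3L, 7L), value = 0, depth = 1L)
  expect_error(write_records(interleaved, p), "sorted")
})

test_that("attach_methylation_tag calls CpG context only", {
  expect_identical(attach_methylation_tag("CGT", "3M", 0L, FALSE, "CGTA"),
                   "Z..")
  expect_identical(attach_methylation_tag("TGT", "3M", 0L, FALSE, "CGTA"),
                   "z..")
  expect_identical(attach_methylation_tag("CAT", "3M", 0L, FALSE, "CATA"),
                   "...")
  # reverse strand: G preceded by C; read G -> Z, A -> z
  expect_identical(attach_methylation_tag("CGT", "3M", 0L, TRUE, "CGTA"),
                   ".Z.")
  expect_identical(attach_methylation_tag("CAT", "3M", 0L, TRUE, "CGTA"),
                   ".z.")
  expect_error(attach_methylation_tag("CGT", "3M", 2L, FALSE, "CGTA"),
               "contig end")
})

test_that("tag round-trips simulator ground truth on both strands", {
  sam <- tempfile(fileext = ".sam")
  fa <- tempfile(fileext = ".fa")
  cfg <- list(locus_config("chrA", c(20L, 24L, 31L, 40L), rep(1 / 16, 16),
                           depth = 30L),
              locus_config("chrA", c(300L, 302L, 304L), rep(1 / 8, 8),
                           depth = 20L))
  simulate_alignments(cfg, seed = 11L, sam_path = sam, fasta_path = fa,
                      reverse_fraction = 0.5)
  orig <- stream_methyl_reads(sam)

  stripped <- tempfile(fileext = ".sam")
  writeLines(sub("\tXM:Z:[^\t]*", "", readLines(sam)), stripped)
  retag <- tempfile(fileext = ".sam")
  tag_alignments(stripped, fa, retag)
  redone <- stream_methyl_reads(retag)

  expect_identical(redone$pos, orig$pos)
  expect_identical(redone$meth, orig$meth)
})

test_that("tag errors on a missing contig", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrZ", "ACGTACGT"), fa)
  sam <- write_test_sam(sam_line("a", 0L, "chr1", 1L, 42L, "4M", "ACGT"))
  expect_error(tag_alignments(sam, fa, tempfile()), "chr1")
})
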