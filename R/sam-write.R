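# Minimal SAM text assembly for the simulator, tagger and trimmer.
# Reading always goes through Rsamtools; writing is plain record formatting.

#' @noRd
.sam_header <- function(targets) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(targets), as.integer(targets)))
}

# records: data.table with qname, flag, chrom, pos (0-based), mapq, cigar,
# seq, qual, xm (NA for untagged). Writes 1-based POS.
#' @noRd
.write_sam <- function(path, targets, records) {
  lines <- .sam_header(targets)
  if (nrow(records)) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                    records$qname, as.integer(records$flag),
                    records$chrom, as.integer(records$pos) + 1L,
                    as.integer(records$mapq), records$cigar,
                    records$seq, records$qual)
    tagged <- !is.na(records$xm)
    body[tagged] <- paste0(body[tagged], "\tXM:Z:", records$xm[tagged])
    lines <- c(lines, body)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Full-record scan used by tag/trim (keeps seq/qual so files can be rewritten).
#' @noRd
.scan_full <- function(path) {
  bam <- .as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  res <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam),
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
      tag = "XM"))[[1L]]
  xm <- res$tag$XM %||% rep(NA_character_, length(res$pos))
  list(targets = hdr$targets,
       records = data.table(
         qname = res$qname,
         flag = res$flag,
         chrom = as.character(res$rname),
         pos = res$pos - 1L,
         mapq = res$mapq,
         cigar = res$cigar,
         seq = as.character(res$seq),
         qual = as.character(res$qual),
         xm = xm))
}

#' @noRd
.sort_sam_records <- function(records, targets) {
  records[order(match(records$chrom, names(targets)), records$pos)]
}
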