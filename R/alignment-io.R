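# Alignment input: SAM/BAM reading, XM call-string decoding, BED-like output.
#
# Coordinates are 0-based throughout the package; Rsamtools' 1-based `pos` is
# converted on entry and SAM text written by the package converts back.

#' @noRd
.as_bam <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE))
  }
  path
}

# Map each query base (1-based offset in SEQ/XM) to its 0-based reference
# offset relative to the alignment start; NA for query bases that do not
# consume reference (insertions, soft clips).
#' @noRd
.cigar_ref_offsets <- function(cigar) {
  ops  <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  if (length(ops) == 0L) stop("malformed CIGAR: '", cigar, "'")
  qlen <- sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  off <- rep.int(NA_integer_, qlen)
  q <- 0L; r <- 0L
  for (t in seq_along(ops)) {
    l <- lens[t]
    op <- ops[t]
    if (op %in% c("M", "=", "X")) {
      off[q + seq_len(l)] <- r + seq_len(l) - 1L
      q <- q + l; r <- r + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    } else if (op %in% c("D", "N")) {
      r <- r + l
    } # H, P consume neither
  }
  list(offsets = off, qlen = qlen, ref_width = r)
}

#' Decode one read's methylation call string into reference-anchored CpG calls
#'
#' Walks the CIGAR and the Bismark-style call string (XM tag) in lockstep.
#' `Z`/`z` characters at aligned query positions become methylated /
#' unmethylated CpG calls at their reference coordinate; every other character
#' (`x`, `X`, `h`, `H`, `u`, `U`, `.`) yields no call.  For reverse-strand
#' alignments the call sits on the G of the CpG, so its coordinate is shifted
#' by -1 and both strands collapse onto the forward-strand C.
#'
#' @param read A list describing one alignment record with elements
#'   `qname`, `flag`, `chrom`, `pos` (0-based leftmost reference coordinate),
#'   `mapq`, `cigar` and `call_string` (the XM tag text).
#' @param mapq_min Minimum mapping quality; lower-quality reads are skipped.
#' @return A `methyl_read` (list with `chrom`, `pos` -- 0-based forward-strand
#'   C coordinates, strictly increasing -- `meth` -- logical, `TRUE` =
#'   methylated -- and `source_length`), or `NULL` when the read is skipped
#'   (unmapped / secondary / supplementary / duplicate / QC-fail flag, low
#'   mapping quality, or zero CpG calls).
#' @examples
#' r <- list(qname = "r1", flag = 0L, chrom = "chr1", pos = 100L, mapq = 42L,
#'           cigar = "9M", call_string = "..Z..H..z")
#' parse_methylation_calls(r)
#' @export
parse_methylation_calls <- function(read, mapq_min = 10L) {
  flag <- as.integer(read$flag)
  if (bitwAnd(flag, .SKIP_MASK) != 0L) return(NULL)
  mapq <- read$mapq %||% 255L
  if (is.na(mapq)) mapq <- 255L
  if (mapq < mapq_min) return(NULL)
  xm <- read$call_string %||% read$xm
  if (is.null(xm) || is.na(xm))
    stop("read '", read$qname %||% "?", "' has no XM methylation call string; ",
         "run the 'tag' subcommand (tag_alignments()) first")
  cm <- .cigar_ref_offsets(read$cigar)
  if (nchar(xm) != cm$qlen)
    stop(sprintf(
      "read '%s': call string length %d does not match query length %d implied by CIGAR '%s'",
      read$qname %||% "?", nchar(xm), cm$qlen, read$cigar))
  m <- gregexpr("[Zz]", xm)[[1L]]
  if (m[1L] == -1L) return(NULL)
  offs <- as.integer(m)
  states <- substring(xm, offs, offs) == "Z"
  ref <- cm$offsets[offs]
  ok <- !is.na(ref)
  if (!any(ok)) return(NULL)
  cpg <- as.integer(read$pos) + ref[ok]
  states <- states[ok]
  if (bitwAnd(flag, .FLAG_REVERSE) != 0L) cpg <- cpg - 1L
  o <- order(cpg)
  cpg <- cpg[o]; states <- states[o]
  if (anyDuplicated(cpg))
    stop("read '", read$qname %||% "?", "': duplicate CpG coordinates in call string")
  structure(list(chrom = as.character(read$chrom), pos = cpg, meth = states,
                 source_length = cm$qlen),
            class = "methyl_read")
}

#' Stream methylation calls from a coordinate-sorted alignment file
#'
#' Reads a coordinate-sorted SAM or BAM file once, applies flag and mapping
#' quality filters, and decodes every kept read's XM call string into
#' reference-anchored binary CpG states.  Reads are returned in file
#' (coordinate) order, which downstream one-sweep accumulators rely on.
#'
#' @param path SAM or BAM file with XM tags (see [tag_alignments()] for
#'   alignments produced by non-Bismark aligners).
#' @param mapq_min Minimum mapping quality (default 10).
#' @return A `methyl_reads` object: parallel vectors/lists `chrom`, `start`
#'   (0-based leftmost aligned position), `qname`, `source_length`, `pos`
#'   (list of 0-based CpG coordinates per read) and `meth` (list of logical
#'   state vectors), plus bookkeeping counts `n_records` (alignment records in
#'   the file), `n_kept` (records passing filters) and `n_with_calls`.
#' @export
stream_methyl_reads <- function(path, mapq_min = 10L) {
  bam <- .as_bam(path)
  res <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam),
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
      tag = "XM"))[[1L]]
  n_rec <- length(res$pos)
  flag <- res$flag

  mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  cid <- as.integer(res$rname)[mapped]
  pp <- res$pos[mapped]
  if (length(cid) > 1L) {
    dc <- diff(cid)
    if (any(dc < 0L) || any(dc == 0L & diff(pp) < 0L))
      stop("input alignments are not coordinate-sorted; ",
           "sort them first (e.g. 'samtools sort')")
  }

  keep <- mapped & bitwAnd(flag, .SKIP_MASK) == 0L
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 255L
  keep <- keep & mapq >= mapq_min
  n_kept <- sum(keep)

  xm <- res$tag$XM %||% rep(NA_character_, n_rec)
  if (anyNA(xm[keep]))
    stop("kept reads lack the XM methylation call string (first: '",
         res$qname[keep][which(is.na(xm[keep]))[1L]],
         "'); run the 'tag' subcommand (tag_alignments()) first")

  qname <- res$qname[keep]
  flag <- flag[keep]
  chrom <- as.character(res$rname)[keep]
  pos0 <- res$pos[keep] - 1L
  cigar <- res$cigar[keep]
  xm <- xm[keep]

  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  bad <- which(nchar(xm) != qlen)
  if (length(bad))
    stop(sprintf(
      "read '%s': call string length %d does not match query length %d implied by CIGAR '%s'",
      qname[bad[1L]], nchar(xm[bad[1L]]), qlen[bad[1L]], cigar[bad[1L]]))

  simple <- cigar == sprintf("%dM", qlen)
  rev <- bitwAnd(flag, .FLAG_REVERSE) != 0L
  mm <- gregexpr("[Zz]", xm)
  n <- length(xm)
  pos_list <- vector("list", n)
  meth_list <- vector("list", n)
  for (i in seq_len(n)) {
    offs <- mm[[i]]
    if (offs[1L] == -1L) {
      pos_list[[i]] <- integer(0)
      next
    }
    offs <- as.integer(offs)
    states <- substring(xm[i], offs, offs) == "Z"
    if (simple[i]) {
      ref <- pos0[i] + offs - 1L
    } else {
      map <- .cigar_ref_offsets(cigar[i])$offsets
      ref <- pos0[i] + map[offs]
      ok <- !is.na(ref)
      ref <- ref[ok]; states <- states[ok]
      if (!length(ref)) {
        pos_list[[i]] <- integer(0)
        next
      }
    }
    if (rev[i]) ref <- ref - 1L
    pos_list[[i]] <- ref
    meth_list[[i]] <- states
  }
  has <- lengths(pos_list) > 0L
  structure(list(chrom = chrom[has], start = pos0[has], qname = qname[has],
                 source_length = qlen[has],
                 pos = pos_list[has],
                 meth = meth_list[has],
                 n_records = n_rec, n_kept = n_kept, n_with_calls = sum(has)),
            class = "methyl_reads")
}

#' @export
print.methyl_reads <- function(x, ...) {
  cat(sprintf("methyl_reads: %d reads with CpG calls (%d records, %d kept)\n",
              length(x$pos), x$n_records, x$n_kept))
  invisible(x)
}

#' @export
length.methyl_reads <- function(x) length(x$pos)

# long-format calls table shared by the sweep accumulators
#' @noRd
.calls_dt <- function(reads) {
  nc <- lengths(reads$pos)
  data.table(
    rid = rep.int(seq_along(reads$pos), nc),
    chrom = rep.int(reads$chrom, nc),
    pos = as.integer(unlist(reads$pos, use.names = FALSE)),
    meth = as.logical(unlist(reads$meth, use.names = FALSE)))
}

# sort records by (chromosome in order of appearance in the stream, start)
#' @noRd
.sort_records <- function(dt, chrom_levels) {
  dt[, chrom := as.character(chrom)]
  setorderv(dt[, .ord := match(chrom, chrom_levels)], c(".ord", "start", "end"))
  dt[, .ord := NULL]
  setcolorder(dt, c("chrom", "start", "end", "value", "depth"))
  dt[]
}

#' @noRd
.empty_records <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             value = numeric(0), depth = integer(0))
}

#' Mean CpG calls per read
#'
#' The mean number of CpG calls per emitted read (lambda) drives the cost
#' ratio between read-centric (n accesses) and CpG-centric (lambda x n
#' accesses) algorithms; RRBS libraries typically have lambda well above 1.
#'
#' @param reads A `methyl_reads` object.
#' @return List with `lambda` (NA for an empty stream) and `histogram`
#'   (a table of calls-per-read).
#' @export
cpgs_per_read_stat <- function(reads) {
  nc <- lengths(reads$pos)
  list(lambda = if (length(nc)) mean(nc) else NA_real_,
       histogram = table(nc))
}

#' Write measure records as BED-like TSV
#'
#' Columns: chrom, start (0-based), end (exclusive), value (6 decimal
#' places), depth.  Records must already be sorted by (chrom, start); per-CpG
#' measures span the CpG dinucleotide (`end = start + 2`).
#'
#' @param records A data.frame/data.table with columns `chrom`, `start`,
#'   `end`, `value`, `depth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  need <- c("chrom", "start", "end", "value", "depth")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  n <- nrow(records)
  if (n > 1L) {
    ch <- as.character(records$chrom)
    runs <- rle(ch)$values
    if (anyDuplicated(runs))
      stop("records are not sorted: chromosome blocks are interleaved")
    same <- ch[-1L] == ch[-n]
    if (any(same & diff(records$start) < 0L))
      stop("records are not sorted by start position")
  }
  lines <- if (n) sprintf("%s\t%d\t%d\t%.6f\t%d",
                          as.character(records$chrom),
                          as.integer(records$start),
                          as.integer(records$end),
                          records$value,
                          as.integer(records$depth))
           else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
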