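# Attach Bismark-style XM call strings to alignments from non-Bismark
# aligners. Only CpG context is called; CHG/CHH positions are emitted as '.'.

#' Compute a methylation call string for one aligned read
#'
#' For a forward-strand read, every aligned query position whose reference
#' base is C immediately followed by G (CpG context) is called: read base C
#' becomes `Z` (methylated, bisulfite-protected), read base T becomes `z`
#' (unmethylated, converted), anything else `.`.  For a reverse-strand read
#' the logic mirrors onto the G of the CpG (reference G preceded by C; read
#' base G -> `Z`, A -> `z`).  All other positions are `.`.
#'
#' @param seq Read bases as stored in the SAM record (forward-strand
#'   projection).
#' @param cigar CIGAR string.
#' @param pos 0-based leftmost reference coordinate.
#' @param reverse Logical; is the read aligned to the reverse strand?
#' @param refseq Reference contig sequence as a single character string.
#' @return The call string (same length as `seq`), a valid XM tag value.
#' @examples
#' attach_methylation_tag("CGT", "3M", 0L, FALSE, "CGTA")  # "Z.."
#' attach_methylation_tag("TGT", "3M", 0L, FALSE, "CGTA")  # "z.."
#' @export
attach_methylation_tag <- function(seq, cigar, pos, reverse, refseq) {
  cm <- .cigar_ref_offsets(cigar)
  if (nchar(seq) != cm$qlen)
    stop(sprintf("SEQ length %d does not match CIGAR '%s'", nchar(seq), cigar))
  reflen <- nchar(refseq)
  if (pos + cm$ref_width > reflen)
    stop("alignment runs off the contig end")
  out <- rep.int(".", cm$qlen)
  aligned <- which(!is.na(cm$offsets))
  if (length(aligned)) {
    r <- pos + cm$offsets[aligned]            # 0-based reference coords
    rb <- substring(refseq, r + 1L, r + 1L)    # reference base at query pos
    qb <- substring(seq, aligned, aligned)
    if (!reverse) {
      nxt <- ifelse(r + 2L <= reflen, substring(refseq, r + 2L, r + 2L), "")
      ctx <- rb == "C" & nxt == "G"
      out[aligned[ctx & qb == "C"]] <- "Z"
      out[aligned[ctx & qb == "T"]] <- "z"
    } else {
      prv <- ifelse(r >= 1L, substring(refseq, r, r), "")
      ctx <- rb == "G" & prv == "C"
      out[aligned[ctx & qb == "G"]] <- "Z"
      out[aligned[ctx & qb == "A"]] <- "z"
    }
  }
  paste(out, collapse = "")
}

#' Add XM methylation call strings to an alignment file
#'
#' Reads a SAM/BAM file and a reference FASTA, computes a CpG-context call
#' string for every mapped read (see [attach_methylation_tag()]) and writes a
#' tagged SAM file that [stream_methyl_reads()] accepts.  Existing XM tags are
#' replaced.  Read orientation is taken from the reverse-strand flag.
#'
#' @param input SAM/BAM path.
#' @param reference Reference FASTA path (contig names must match the
#'   alignment header).
#' @param output Output SAM path.
#' @return `output`, invisibly.  Reads running off the contig end are skipped
#'   with a warning.
#' @export
tag_alignments <- function(input, reference, output) {
  fa <- Biostrings::readDNAStringSet(reference)
  names(fa) <- sub("\\s.*$", "", names(fa))
  scan <- .scan_full(input)
  rec <- scan$records
  missing_contig <- setdiff(unique(rec$chrom[!is.na(rec$pos)]), names(fa))
  if (length(missing_contig))
    stop("reference FASTA lacks contig(s): ",
         paste(missing_contig, collapse = ", "))
  refs <- vapply(as.character(names(fa)), function(n) as.character(fa[[n]]),
                 character(1))
  n_skip <- 0L
  keep <- rep(TRUE, nrow(rec))
  xm <- rec$xm
  for (i in seq_len(nrow(rec))) {
    if (is.na(rec$pos[i]) || bitwAnd(rec$flag[i], .FLAG_UNMAPPED) != 0L) next
    res <- tryCatch(
      attach_methylation_tag(rec$seq[i], rec$cigar[i], rec$pos[i],
                             bitwAnd(rec$flag[i], .FLAG_REVERSE) != 0L,
                             refs[[rec$chrom[i]]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("contig end", conditionMessage(res))) {
        keep[i] <- FALSE
        n_skip <- n_skip + 1L
        next
      }
      stop("read '", rec$qname[i], "': ", conditionMessage(res))
    }
    xm[i] <- res
  }
  if (n_skip > 0L)
    warning(n_skip, " read(s) running off the contig end were skipped")
  rec$xm <- xm
  .write_sam(output, scan$targets, rec[keep])
  invisible(output)
}
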