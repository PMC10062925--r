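# 3'-end trimming of tagged alignments, used to mimic shorter read lengths.
# The 3' end is the end in *read orientation*: the reference-right end for
# forward reads, the reference-left end for reverse reads (whose SAM SEQ is
# stored as the forward-strand projection).

# Slice a CIGAR to query bases [qs, qe] (1-based, inclusive).
# Returns list(cigar, ref_shift) where ref_shift is the reference consumed
# by the dropped query prefix.
#' @noRd
.cigar_slice <- function(cigar, qs, qe) {
  ops  <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  out_ops <- character(0)
  out_lens <- integer(0)
  q <- 0L
  ref_shift <- 0L
  for (t in seq_along(ops)) {
    op <- ops[t]; l <- lens[t]
    qcons <- op %in% c("M", "I", "S", "=", "X")
    rcons <- op %in% c("M", "D", "N", "=", "X")
    if (qcons) {
      lo <- max(q + 1L, qs)
      hi <- min(q + l, qe)
      if (hi >= lo) {
        out_ops <- c(out_ops, op)
        out_lens <- c(out_lens, hi - lo + 1L)
      }
      if (rcons && q + 1L < qs)
        ref_shift <- ref_shift + min(q + l, qs - 1L) - q
      q <- q + l
    } else if (rcons) {
      # D/N: keep only when strictly inside the kept query range
      if (q + 1L > qs && q < qe) {
        out_ops <- c(out_ops, op)
        out_lens <- c(out_lens, l)
      } else if (q + 1L <= qs) {
        ref_shift <- ref_shift + l
      }
    }
    if (q >= qe && !qcons && t < length(ops)) break
  }
  # drop dangling trailing D/N
  while (length(out_ops) && out_ops[length(out_ops)] %in% c("D", "N")) {
    out_ops <- out_ops[-length(out_ops)]
    out_lens <- out_lens[-length(out_lens)]
  }
  while (length(out_ops) && out_ops[1L] %in% c("D", "N")) {
    ref_shift <- ref_shift + out_lens[1L]
    out_ops <- out_ops[-1L]
    out_lens <- out_lens[-1L]
  }
  list(cigar = paste0(out_lens, out_ops, collapse = ""),
       ref_shift = ref_shift)
}

#' Trim tagged alignments from the 3' end to target read lengths
#'
#' For each target length, truncates SEQ, QUAL, the XM call string and the
#' CIGAR of every read to its first `target_length` query bases in read
#' orientation: forward reads lose their reference-right end, reverse reads
#' lose their reference-left end (their `pos` advances accordingly).  One
#' coordinate-sorted SAM file is written per target length.  Reads already
#' shorter than the target are left unmodified and counted as warnings.
#'
#' @param input Tagged SAM/BAM path.
#' @param target_lengths Integer vector of target read lengths in bp.
#' @param out_dir Output directory (created if needed).
#' @param prefix Output file name prefix (default: input base name).
#' @return Named character vector mapping `"<length>"` to the written SAM
#'   path.
#' @export
trim_calls_3prime <- function(input, target_lengths, out_dir,
                              prefix = NULL) {
  scan <- .scan_full(input)
  rec <- scan$records
  if (any(is.na(rec$xm[!is.na(rec$pos)])))
    stop("input reads are not tagged; run the 'tag' subcommand first")
  if (is.null(prefix))
    prefix <- sub("\\.(sam|bam)$", "", basename(input), ignore.case = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(rec$cigar)
  rev <- bitwAnd(rec$flag, .FLAG_REVERSE) != 0L
  simple <- rec$cigar == sprintf("%dM", qlen)
  out <- character(0)
  for (L in as.integer(target_lengths)) {
    r2 <- copy(rec)
    todo <- which(qlen > L)
    n_short <- sum(qlen < L)
    if (n_short > 0L)
      warning(sprintf("%d read(s) shorter than %d bp left unmodified", n_short, L))
    for (i in todo) {
      qs <- if (rev[i]) qlen[i] - L + 1L else 1L
      qe <- if (rev[i]) qlen[i] else L
      if (simple[i]) {
        cg <- sprintf("%dM", L)
        shift <- if (rev[i]) qlen[i] - L else 0L
      } else {
        sl <- .cigar_slice(rec$cigar[i], qs, qe)
        cg <- sl$cigar
        shift <- sl$ref_shift
      }
      set(r2, i, "cigar", cg)
      set(r2, i, "pos", rec$pos[i] + shift)
      set(r2, i, "seq", substring(rec$seq[i], qs, qe))
      set(r2, i, "qual", substring(rec$qual[i], qs, qe))
      set(r2, i, "xm", substring(rec$xm[i], qs, qe))
    }
    r2 <- .sort_sam_records(r2, scan$targets)
    path <- file.path(out_dir, sprintf("%s_%dbp.sam", prefix, L))
    .write_sam(path, scan$targets, r2)
    out[as.character(L)] <- path
  }
  out
}
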