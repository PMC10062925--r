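# Ground-truthed RRBS-like read simulator. Each locus has k CpGs and an
# epiallele distribution over the 2^k binary patterns; every simulated read
# draws one pattern, so every measure has a closed-form expectation that the
# streaming implementations can be checked against.

#' Describe one simulated locus
#'
#' @param chrom Chromosome name.
#' @param cpg_pos Strictly increasing 0-based coordinates of the CpG
#'   cytosines (first must be >= 5 to leave room for the random read start
#'   offset).
#' @param epiallele_probs Probability vector of length `2^k` over the binary
#'   methylation patterns of the locus's `k` CpGs.  Pattern `i` (0-based) has
#'   bit `j` set when the `(j+1)`-th CpG is methylated (bit 0 = leftmost).
#' @param depth Number of reads to draw.
#' @param read_length Read length in bp (default 50).
#' @param call_error Probability that a stored call flips state (default 0).
#' @return A `locus_config` list.
#' @export
locus_config <- function(chrom, cpg_pos, epiallele_probs, depth,
                         read_length = 50L, call_error = 0) {
  cpg_pos <- as.integer(cpg_pos)
  k <- length(cpg_pos)
  stopifnot(k >= 1L, !is.unsorted(cpg_pos, strictly = TRUE), cpg_pos[1L] >= 5L,
            length(epiallele_probs) == 2^k, all(epiallele_probs >= 0),
            abs(sum(epiallele_probs) - 1) < 1e-8,
            depth >= 0L, read_length >= 2L, call_error >= 0, call_error <= 1)
  structure(list(chrom = chrom, cpg_pos = cpg_pos,
                 epiallele_probs = epiallele_probs / sum(epiallele_probs),
                 depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 call_error = call_error),
            class = "locus_config")
}

# 2^k x k logical matrix; bits[i, j] = bit (j-1) of pattern (i-1)
#' @noRd
.pattern_bits <- function(k) {
  i <- 0:(2^k - 1L)
  vapply(seq_len(k),
         function(j) bitwAnd(bitwShiftR(i, j - 1L), 1L) == 1L,
         logical(2^k))
}

#' Closed-form measure expectations under an epiallele distribution
#'
#' Computes, by exhaustive enumeration over patterns and pattern pairs, the
#' error-free expectation of every measure for a locus whose reads all cover
#' all `k` CpGs.  This is an implementation path independent of the streaming
#' accumulators and serves as their oracle.
#'
#' @param probs Probability vector over the `2^k` patterns (bit convention as
#'   in [locus_config()]).
#' @param cpg_pos Optional CpG coordinates, required for LPMD (pair
#'   distances).
#' @param d_min,d_max LPMD distance window (defaults 2 and 16).
#' @param min_cpgs PDR classification threshold (default 4).
#' @return Named numeric vector: `pdr`, `pm`, `me`, `mhl`, `lpmd`, `fdrp`,
#'   `qfdrp`.  `pm`/`me` are means over the sliding 4-CpG marginal quartets
#'   (`NA` when k < 4); `pdr` is `NA` when k < `min_cpgs`; `lpmd` is `NA`
#'   when no pair falls in the window or `cpg_pos` is missing.
#' @export
analytic_measures <- function(probs, cpg_pos = NULL, d_min = 2L, d_max = 16L,
                              min_cpgs = 4L) {
  k <- as.integer(round(log2(length(probs))))
  if (2^k != length(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be a probability vector of length 2^k")
  probs <- probs / sum(probs)
  bits <- .pattern_bits(k)
  nmeth <- rowSums(bits)
  mixed <- nmeth > 0L & nmeth < k

  pdr <- if (k >= min_cpgs) sum(probs[mixed]) else NA_real_

  pm <- me <- NA_real_
  if (k >= 4L) {
    wins <- seq_len(k - 3L)
    pms <- mes <- numeric(length(wins))
    for (w in wins) {
      code <- as.integer(bits[, w]) + 2L * bits[, w + 1L] +
              4L * bits[, w + 2L] + 8L * bits[, w + 3L]
      q <- vapply(0:15, function(cc) sum(probs[code == cc]), numeric(1))
      pms[w] <- 1 - sum(q * q)
      nz <- q > 0
      mes[w] <- -sum(q[nz] * log2(q[nz])) / 4
    }
    pm <- mean(pms)
    me <- mean(mes)
  }

  # MHL: all haplotypes have length k, so P(MH_i) = E[# length-i methylated
  # runs' substrings] / (k - i + 1)
  num <- numeric(k)
  for (pidx in which(probs > 0)) {
    r <- rle(bits[pidx, ])
    for (run in r$lengths[r$values]) {
      j <- seq_len(run)
      num[j] <- num[j] + probs[pidx] * (run - j + 1)
    }
  }
  i <- seq_len(k)
  mhl <- sum(i * (num / (k - i + 1))) / sum(i)

  lpmd <- NA_real_
  if (!is.null(cpg_pos)) {
    stopifnot(length(cpg_pos) == k)
    dsum <- 0; npair <- 0L
    if (k >= 2L) {
      for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
        dd <- cpg_pos[b] - cpg_pos[a]
        if (dd >= d_min && dd <= d_max) {
          npair <- npair + 1L
          dsum <- dsum + sum(probs[bits[, a] != bits[, b]])
        }
      }
    }
    if (npair > 0L) lpmd <- dsum / npair
  }

  fdrp <- 1 - sum(probs * probs)
  marg <- colSums(bits * probs)
  qfdrp <- sum(2 * marg * (1 - marg)) / k

  c(pdr = pdr, pm = pm, me = me, mhl = mhl, lpmd = lpmd,
    fdrp = fdrp, qfdrp = qfdrp)
}

#' Simulate tagged bisulfite alignments with known ground truth
#'
#' For each locus, `depth` epialleles are drawn i.i.d. from its
#' `epiallele_probs`; each becomes one read whose XM call string encodes the
#' drawn states (independently flipped with probability `call_error`).  Reads
#' start at the locus's first CpG minus a uniform 0-5 bp offset, mimicking
#' restriction-site anchoring in RRBS.  Output is coordinate-sorted,
#' header-complete SAM accepted by [stream_methyl_reads()]; an optional
#' reference FASTA (CG at each CpG, A elsewhere) supports
#' [tag_alignments()] round trips.
#'
#' @param configs List of [locus_config()] objects; loci on one chromosome
#'   must not overlap.
#' @param seed Integer seed; all randomness derives from it.
#' @param sam_path Output SAM path.
#' @param fasta_path Optional reference FASTA path.
#' @param reverse_fraction Fraction of reads simulated on the reverse strand
#'   (default 0).
#' @param compute_truth Compute per-locus [analytic_measures()] (default
#'   TRUE; disable for large runs where only the reads matter).
#' @param d_min,d_max LPMD window forwarded to [analytic_measures()].
#' @return List with `sam` (path), `fasta` (path or NULL), `truth`
#'   (data.table of per-locus analytic values, or NULL) and `targets`
#'   (named contig lengths).
#' @export
simulate_alignments <- function(configs, seed, sam_path, fasta_path = NULL,
                                reverse_fraction = 0, compute_truth = TRUE,
                                d_min = 2L, d_max = 16L) {
  if (inherits(configs, "locus_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L,
            all(vapply(configs, inherits, logical(1), "locus_config")))
  set.seed(as.integer(seed))

  # overlap check per chromosome (span includes the max 5 bp start offset
  # and the CpG's G)
  spans <- data.table(
    chrom = vapply(configs, `[[`, character(1), "chrom"),
    lo = vapply(configs, function(cf) cf$cpg_pos[1L] - 5L, integer(1)),
    hi = vapply(configs, function(cf)
      max(cf$cpg_pos[length(cf$cpg_pos)] + 2L,
          cf$cpg_pos[1L] + cf$read_length), integer(1)))
  spans[, locus := .I]
  setorderv(spans, c("chrom", "lo"))
  ov <- spans[, any(lo[-1L] < hi[-.N]), by = chrom][V1 == TRUE]
  if (nrow(ov))
    stop("loci overlap on chromosome(s): ", paste(ov$chrom, collapse = ", "))

  chroms <- unique(vapply(configs, `[[`, character(1), "chrom"))
  targets <- vapply(chroms, function(ch) {
    hi <- max(spans[chrom == ch, hi])
    as.integer(hi + 10L)
  }, integer(1))

  bits_cache <- list()
  recs <- vector("list", length(configs))
  truth <- if (compute_truth) vector("list", length(configs)) else NULL

  for (li in seq_along(configs)) {
    cf <- configs[[li]]
    k <- length(cf$cpg_pos)
    kk <- as.character(k)
    if (is.null(bits_cache[[kk]])) bits_cache[[kk]] <- .pattern_bits(k)
    bits <- bits_cache[[kk]]

    if (compute_truth) {
      tv <- analytic_measures(cf$epiallele_probs, cf$cpg_pos,
                              d_min = d_min, d_max = d_max)
      truth[[li]] <- data.table(
        locus = li, chrom = cf$chrom,
        start = cf$cpg_pos[1L], end = cf$cpg_pos[k] + 2L,
        k = k, depth = cf$depth, t(tv))
    }
    if (cf$depth == 0L) next

    draw <- sample.int(2^k, cf$depth, replace = TRUE,
                       prob = cf$epiallele_probs)
    offset <- sample.int(6L, cf$depth, replace = TRUE) - 1L
    rstart <- cf$cpg_pos[1L] - offset
    rev <- stats::runif(cf$depth) < reverse_fraction
    states <- bits[draw, , drop = FALSE]
    if (cf$call_error > 0) {
      flip <- matrix(stats::runif(cf$depth * k) < cf$call_error,
                     nrow = cf$depth)
      states <- xor(states, flip)
    }

    L <- cf$read_length
    qual <- strrep("I", L)
    seqs <- character(cf$depth)
    xms <- character(cf$depth)
    for (ri in seq_len(cf$depth)) {
      sq <- rep.int("A", L)
      xm <- rep.int(".", L)
      st <- rstart[ri]
      for (j in seq_len(k)) {
        qc <- cf$cpg_pos[j] - st + 1L   # 1-based query offset of the C
        qg <- qc + 1L                   # ... of the G
        if (!rev[ri]) {
          if (qc >= 1L && qc <= L) {
            sq[qc] <- if (states[ri, j]) "C" else "T"
            xm[qc] <- if (states[ri, j]) "Z" else "z"
          }
          if (qg >= 1L && qg <= L) sq[qg] <- "G"
        } else {
          if (qc >= 1L && qc <= L) sq[qc] <- "C"
          if (qg >= 1L && qg <= L) {
            sq[qg] <- if (states[ri, j]) "G" else "A"
            xm[qg] <- if (states[ri, j]) "Z" else "z"
          }
        }
      }
      seqs[ri] <- paste(sq, collapse = "")
      xms[ri] <- paste(xm, collapse = "")
    }
    recs[[li]] <- data.table(
      qname = sprintf("locus%d_read%d", li, seq_len(cf$depth)),
      flag = ifelse(rev, 16L, 0L),
      chrom = cf$chrom, pos = rstart, mapq = 42L,
      cigar = sprintf("%dM", L), seq = seqs, qual = qual, xm = xms)
  }

  records <- rbindlist(recs)
  if (nrow(records)) records <- .sort_sam_records(records, targets)
  else records <- data.table(qname = character(0), flag = integer(0),
                             chrom = character(0), pos = integer(0),
                             mapq = integer(0), cigar = character(0),
                             seq = character(0), qual = character(0),
                             xm = character(0))
  .write_sam(sam_path, targets, records)

  if (!is.null(fasta_path)) {
    seqs <- lapply(chroms, function(ch) {
      v <- rep.int("A", targets[[ch]])
      for (cf in configs) if (cf$chrom == ch) {
        v[cf$cpg_pos + 1L] <- "C"
        v[cf$cpg_pos + 2L] <- "G"
      }
      paste(v, collapse = "")
    })
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- chroms
    Biostrings::writeXStringSet(dss, fasta_path)
  }

  list(sam = sam_path, fasta = fasta_path,
       truth = if (compute_truth) rbindlist(truth) else NULL,
       targets = targets)
}
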