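# Epiallele diversity over CpG quartets: epipolymorphism (PM) and
# methylation entropy (ME). A quartet is a sliding window of 4 consecutive
# CpG calls within a read; its identity is the exact 4-coordinate tuple.

#' Extract CpG quartet observations from one read
#'
#' A read with `c` calls yields `max(0, c - 3)` observations, one per sliding
#' window of 4 consecutive calls.  The pattern encodes the 4 states as a
#' 4-bit integer with bit 0 = state of the first (leftmost) CpG.
#'
#' @param mread A `methyl_read`.
#' @return A data.table with columns `chrom`, `p1`..`p4` (0-based CpG
#'   coordinates) and `pat` (0..15); zero rows when the read has < 4 calls.
#' @export
extract_quartets <- function(mread) {
  p <- mread$pos
  m <- as.integer(mread$meth)
  cc <- length(p)
  if (cc < 4L)
    return(data.table(chrom = character(0), p1 = integer(0), p2 = integer(0),
                      p3 = integer(0), p4 = integer(0), pat = integer(0)))
  idx <- seq_len(cc - 3L)
  data.table(chrom = mread$chrom,
             p1 = p[idx], p2 = p[idx + 1L], p3 = p[idx + 2L], p4 = p[idx + 3L],
             pat = m[idx] + 2L * m[idx + 1L] + 4L * m[idx + 2L] +
                   8L * m[idx + 3L])
}

#' @noRd
.quartets_dt <- function(reads) {
  n <- length(reads$pos)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- reads$pos[[i]]
    cc <- length(p)
    if (cc < 4L) next
    m <- as.integer(reads$meth[[i]])
    idx <- seq_len(cc - 3L)
    out[[i]] <- list(chrom = reads$chrom[i],
                     p1 = p[idx], p2 = p[idx + 1L],
                     p3 = p[idx + 2L], p4 = p[idx + 3L],
                     pat = m[idx] + 2L * m[idx + 1L] + 4L * m[idx + 2L] +
                           8L * m[idx + 3L])
  }
  rbindlist(lapply(out[!vapply(out, is.null, logical(1))], as.data.table))
}

#' Epipolymorphism of a quartet pattern count vector
#'
#' `PM = 1 - sum(p_i^2)` over the 16 pattern frequencies; ranges from 0
#' (single pattern) to 15/16 (uniform).
#'
#' @param counts Non-negative integer vector of length 16 (pattern-indexed
#'   counts; total must be >= 1).
#' @return PM in \[0, 15/16\].
#' @export
epipolymorphism <- function(counts) {
  stopifnot(length(counts) == 16L)
  n <- sum(counts)
  if (n < 1L) stop("zero total pattern count; enforce depth upstream")
  p <- counts / n
  1 - sum(p * p)
}

#' Methylation entropy of a quartet pattern count vector
#'
#' `ME = -(1/4) * sum(p_i * log2(p_i))` with `0 * log 0 = 0`; ranges from 0
#' (single pattern) to 1 (uniform over the 16 patterns).
#'
#' @inheritParams epipolymorphism
#' @return ME in \[0, 1\].
#' @export
methylation_entropy <- function(counts) {
  stopifnot(length(counts) == 16L)
  n <- sum(counts)
  if (n < 1L) stop("zero total pattern count; enforce depth upstream")
  p <- counts[counts > 0] / n
  -sum(p * log2(p)) / 4
}

#' Epipolymorphism and methylation entropy per CpG quartet
#'
#' Accumulates 16-bin pattern counts keyed by the exact 4-coordinate tuple in
#' one sweep and emits PM and ME for quartets meeting the depth threshold.
#' The record interval spans the first CpG's C through the last CpG's G.
#'
#' @inheritParams compute_pdr
#' @param min_depth Minimum number of pattern observations (default 10).
#' @return List with elements `pm` and `me`, each a record data.table as in
#'   [compute_pdr()] (with `end = p4 + 2`).
#' @export
compute_pm_me <- function(reads, min_depth = 10L) {
  qt <- .quartets_dt(reads)
  if (!nrow(qt))
    return(list(pm = .empty_records(), me = .empty_records()))
  grp <- qt[, {
    cnt <- tabulate(pat + 1L, 16L)
    p <- cnt / .N
    nz <- p > 0
    .(depth = .N,
      pm = 1 - sum(p * p),
      me = -sum(p[nz] * log2(p[nz])) / 4)
  }, by = .(chrom, p1, p2, p3, p4)]
  grp <- grp[depth >= min_depth]
  if (!nrow(grp))
    return(list(pm = .empty_records(), me = .empty_records()))
  lev <- unique(reads$chrom)
  grp[, .ord := match(chrom, lev)]
  setorderv(grp, c(".ord", "p1", "p2", "p3", "p4"))
  grp[, .ord := NULL]
  list(pm = .sort_records(grp[, .(chrom, start = p1, end = p4 + 2L,
                                  value = pm, depth = as.integer(depth))], lev),
       me = .sort_records(grp[, .(chrom, start = p1, end = p4 + 2L,
                                  value = me, depth = as.integer(depth))], lev))
}
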