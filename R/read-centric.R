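# Read-centric one-sweep measures: PDR (per CpG), MHL (per CpG), LPMD
# (global, per CpG pair, per distance).

#' Classify one read as concordant or discordant
#'
#' A read is discordant when it carries both a methylated and an
#' unmethylated CpG call; reads with fewer than `min_cpgs` calls are left
#' unclassified and do not enter PDR.
#'
#' @param mread A `methyl_read` (see [parse_methylation_calls()]).
#' @param min_cpgs Minimum number of CpG calls required for classification
#'   (default 4, following the original PDR definition; the read-wise
#'   discordance notion itself only needs 2).
#' @return One of `"CONCORDANT"`, `"DISCORDANT"`, `"UNCLASSIFIED"`.
#' @export
classify_read <- function(mread, min_cpgs = 4L) {
  m <- mread$meth
  if (length(m) < min_cpgs) return("UNCLASSIFIED")
  if (any(m) && !all(m)) "DISCORDANT" else "CONCORDANT"
}

# vectorized classification over a methyl_reads stream:
# NA = unclassified, TRUE = discordant, FALSE = concordant
#' @noRd
.classify_all <- function(reads, min_cpgs) {
  disc <- vapply(reads$meth, function(m) any(m) && !all(m), logical(1))
  disc[lengths(reads$meth) < min_cpgs] <- NA
  disc
}

#' Proportion of discordant reads (PDR) per CpG
#'
#' Each classified read increments the counters of every CpG it calls; per
#' CpG, PDR is the fraction of classified covering reads that are discordant.
#' Computed in a single pass over the sorted stream.
#'
#' @param reads A `methyl_reads` stream from [stream_methyl_reads()].
#' @param min_depth Minimum classified-read depth for a CpG to be reported
#'   (default 10).
#' @param min_cpgs See [classify_read()].
#' @return A data.table of records (`chrom`, `start`, `end = start + 2`,
#'   `value`, `depth`), sorted by (chrom, start).
#' @export
compute_pdr <- function(reads, min_depth = 10L, min_cpgs = 4L) {
  disc <- .classify_all(reads, min_cpgs)
  dt <- .calls_dt(reads)
  dt[, disc := disc[rid]]
  dt <- dt[!is.na(disc)]
  if (!nrow(dt)) return(.empty_records())
  out <- dt[, .(depth = .N, value = sum(disc) / .N), by = .(chrom, pos)]
  out <- out[depth >= min_depth]
  if (!nrow(out)) return(.empty_records())
  .sort_records(out[, .(chrom, start = pos, end = pos + 2L, value,
                        depth = as.integer(depth))],
                unique(reads$chrom))
}

#' Accumulate same-read CpG pair observations for LPMD
#'
#' For every pair of calls within `mread` whose genomic distance (between the
#' forward-strand C coordinates) lies in `[d_min, d_max]`, records one
#' concordant or discordant observation.
#'
#' @param mread A `methyl_read`.
#' @param counter A pair counter as returned by a previous call, or `NULL` to
#'   start one (a data.table keyed by `chrom`, `pos`, `pos2`).
#' @param d_min,d_max Distance window in bp (defaults 2 and 16).
#' @return The updated counter.
#' @export
accumulate_lpmd <- function(mread, counter = NULL, d_min = 2L, d_max = 16L) {
  stopifnot(d_min >= 1L, d_min <= d_max)
  p <- mread$pos
  m <- mread$meth
  new <- NULL
  if (length(p) >= 2L) {
    idx <- which(outer(p, p, function(a, b) {
      dd <- b - a
      dd >= d_min & dd <= d_max
    }), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    if (nrow(idx))
      new <- data.table(chrom = mread$chrom,
                        pos = p[idx[, 1L]], pos2 = p[idx[, 2L]],
                        n_concordant = as.integer(m[idx[, 1L]] == m[idx[, 2L]]),
                        n_discordant = as.integer(m[idx[, 1L]] != m[idx[, 2L]]))
  }
  out <- rbindlist(list(counter, new))
  if (!nrow(out))
    return(data.table(chrom = character(0), pos = integer(0),
                      pos2 = integer(0), n_concordant = integer(0),
                      n_discordant = integer(0)))
  out[, .(n_concordant = sum(n_concordant), n_discordant = sum(n_discordant)),
      by = .(chrom, pos, pos2)]
}

#' Local pairwise methylation discordance (LPMD)
#'
#' LPMD is the fraction of same-read CpG pairs, at genomic distances within
#' `[d_min, d_max]` bp, whose two methylation states differ.  Because pairs
#' are conditioned on a fixed distance window, the measure is comparable
#' across read lengths, unlike PDR.
#'
#' @inheritParams compute_pdr
#' @param d_min,d_max Distance window in bp between the forward-strand C
#'   coordinates of the two CpGs (defaults 2 and 16).
#' @param min_pair_depth Minimum co-observations for a pair to appear in the
#'   per-pair output (default 4); the pooled global value uses all pairs.
#' @return List with `global` (pooled discordant fraction, `NA` when no
#'   eligible pair exists), `pairs` (records with `start` = first C,
#'   `end` = second C + 2), and `by_distance` (data.table `distance`,
#'   `n_pairs`, `lpmd` for each distance in the window).
#' @export
compute_lpmd <- function(reads, d_min = 2L, d_max = 16L, min_pair_depth = 4L) {
  stopifnot(d_min >= 1L, d_min <= d_max)
  dt <- .calls_dt(reads)
  empty_bd <- data.table(distance = seq.int(d_min, d_max), n_pairs = 0L,
                         lpmd = NA_real_)
  if (!nrow(dt))
    return(list(global = NA_real_, pairs = .empty_records(),
                by_distance = empty_bd))
  right <- dt[, .(rid, pos2 = pos, meth2 = meth)]
  pairs <- right[dt, on = "rid", allow.cartesian = TRUE]
  pairs <- pairs[pos2 - pos >= d_min & pos2 - pos <= d_max]
  if (!nrow(pairs))
    return(list(global = NA_real_, pairs = .empty_records(),
                by_distance = empty_bd))
  pairs[, disc := meth != meth2]
  global <- sum(pairs$disc) / nrow(pairs)
  per_pair <- pairs[, .(depth = .N, value = sum(disc) / .N),
                    by = .(chrom, pos, pos2)]
  per_pair <- per_pair[depth >= min_pair_depth]
  rec <- if (nrow(per_pair))
    .sort_records(per_pair[, .(chrom, start = pos, end = pos2 + 2L, value,
                               depth = as.integer(depth))],
                  unique(reads$chrom))
  else .empty_records()
  bd <- pairs[, .(n_pairs = .N, lpmd = sum(disc) / .N),
              by = .(distance = pos2 - pos)]
  bd <- bd[data.table(distance = seq.int(d_min, d_max)), on = "distance"]
  bd[is.na(n_pairs), n_pairs := 0L]
  setorderv(bd, "distance")
  list(global = global, pairs = rec, by_distance = bd[])
}

#' Methylation haplotype load of a haplotype multiset
#'
#' For substring lengths `i = 1..L` (L = longest haplotype), `P(MH_i)` is the
#' fraction of contiguous length-`i` substrings, pooled over all haplotypes,
#' that are fully methylated.  MHL is the length-weighted average
#' `sum(i * P(MH_i)) / sum(i)`; lengths with no substrings are excluded from
#' both sums.
#'
#' @param haps Non-empty list of logical vectors (`TRUE` = methylated), one
#'   per read.
#' @return MHL in \[0, 1\].
#' @examples
#' mhl_from_haplotypes(list(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)))
#' # (1*2/3 + 2*1/2 + 3*0) / 6 = 5/18
#' @export
mhl_from_haplotypes <- function(haps) {
  if (!length(haps)) stop("empty haplotype set; enforce a depth threshold upstream")
  L <- max(lengths(haps))
  num <- numeric(L)
  tot <- numeric(L)
  for (h in haps) {
    l <- length(h)
    i <- seq_len(l)
    tot[i] <- tot[i] + (l - i + 1)
    r <- rle(as.logical(h))
    for (run in r$lengths[r$values]) {
      j <- seq_len(run)
      num[j] <- num[j] + (run - j + 1)
    }
  }
  ok <- tot > 0
  w <- seq_len(L)
  sum(w[ok] * (num[ok] / tot[ok])) / sum(w[ok])
}

#' Methylation haplotype load (MHL) per CpG
#'
#' For each CpG, the haplotype set consists of the full contiguous call
#' vector of every read covering it; [mhl_from_haplotypes()] is applied when
#' the depth threshold is met.  Single sweep over the sorted stream.
#'
#' @inheritParams compute_pdr
#' @return A data.table of records as in [compute_pdr()].
#' @export
compute_mhl <- function(reads, min_depth = 10L) {
  dt <- .calls_dt(reads)
  if (!nrow(dt)) return(.empty_records())
  grp <- dt[, .(rids = list(rid)), by = .(chrom, pos)]
  grp[, depth := lengths(rids)]
  grp <- grp[depth >= min_depth]
  if (!nrow(grp)) return(.empty_records())
  grp[, value := vapply(rids, function(ii) mhl_from_haplotypes(reads$meth[ii]),
                        numeric(1))]
  .sort_records(grp[, .(chrom, start = pos, end = pos + 2L, value,
                        depth = as.integer(depth))],
                unique(reads$chrom))
}
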