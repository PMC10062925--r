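# FDRP / qFDRP per CpG via bounded-size reservoir sampling of covering reads.
#
# Exhaustive all-pairs comparison per CpG is quadratic in depth; a uniform
# reservoir (Algorithm R) caps the per-CpG sample at `capacity` reads, the
# device behind the large FDRP/qFDRP speedups.  When capacity >= depth the
# result is exactly the exhaustive one.

#' Create an empty read reservoir
#'
#' @param capacity Maximum number of stored items.
#' @return A reservoir: list with `capacity`, `seen` and `sample`.
#' @export
reservoir_new <- function(capacity) {
  stopifnot(capacity >= 1L)
  list(capacity = as.integer(capacity), seen = 0L, sample = list())
}

#' Offer one item to a reservoir (Algorithm R)
#'
#' The first `capacity` items are stored; thereafter item `k` (1-based)
#' replaces a uniformly chosen slot with probability `capacity / k`, so any
#' prefix of offers leaves each offered item in the sample with equal
#' probability.
#'
#' @param res A reservoir from [reservoir_new()].
#' @param item The item to offer.
#' @param draw Optional integer in `1..seen` overriding the random draw
#'   (slots `<= capacity` replace; larger values leave the sample unchanged).
#'   Used to enumerate the decision space in tests; by default the draw comes
#'   from the session RNG.
#' @return The updated reservoir.
#' @export
reservoir_offer <- function(res, item, draw = NULL) {
  res$seen <- res$seen + 1L
  if (res$seen <= res$capacity) {
    res$sample[[res$seen]] <- item
  } else {
    j <- if (is.null(draw)) sample.int(res$seen, 1L) else as.integer(draw)
    if (j <= res$capacity) res$sample[[j]] <- item
  }
  res
}

#' Discordance between two reads over their shared CpGs
#'
#' @param a,b `methyl_read` objects (or lists with `pos` and `meth`).
#' @return `NULL` when the reads share no CpG position (the pair is excluded
#'   from FDRP and qFDRP); otherwise a list with `shared` (number of common
#'   positions), `hamming` (state mismatches over them) and `discordant`
#'   (`hamming >= 1`).
#' @export
pair_discordance <- function(a, b) {
  ia <- match(a$pos, b$pos)
  sel <- !is.na(ia)
  shared <- sum(sel)
  if (shared == 0L) return(NULL)
  hamming <- sum(a$meth[sel] != b$meth[ia[sel]])
  list(shared = shared, hamming = as.integer(hamming),
       discordant = hamming > 0L)
}

# all-pairs FDRP/qFDRP over a sample of reads covering one CpG;
# returns c(n_retained, n_discordant, qsum)
#' @noRd
.pairs_eval <- function(pos_l, meth_l, min_overlap) {
  s <- length(pos_l)
  k1 <- length(pos_l[[1L]])
  same <- s > 60L && all(lengths(pos_l) == k1) && k1 <= 16L &&
    all(vapply(pos_l, function(p) identical(p, pos_l[[1L]]), logical(1)))
  if (same && k1 >= min_overlap) {
    # identical position signature: vectorize via bit patterns
    pats <- vapply(meth_l,
                   function(m) sum(bitwShiftL(1L, seq_along(m) - 1L) * m),
                   numeric(1))
    bitcnt <- vapply(0:(2^k1 - 1L), function(x) sum(bitwAnd(bitwShiftR(x, 0:(k1 - 1L)), 1L)),
                     numeric(1))
    xo <- outer(as.integer(pats), as.integer(pats), bitwXor)
    hm <- matrix(bitcnt[xo + 1L], nrow = s)
    up <- upper.tri(hm)
    nret <- sum(up)
    return(c(nret, sum(hm[up] > 0), sum(hm[up]) / k1))
  }
  nret <- 0L; ndisc <- 0L; qsum <- 0
  mo <- max(1L, min_overlap)
  for (a in seq_len(s - 1L)) {
    pa <- pos_l[[a]]; ma <- meth_l[[a]]
    for (b in seq.int(a + 1L, s)) {
      ia <- match(pa, pos_l[[b]])
      sel <- !is.na(ia)
      sh <- sum(sel)
      if (sh < mo) next
      hm <- sum(ma[sel] != meth_l[[b]][ia[sel]])
      nret <- nret + 1L
      if (hm > 0L) ndisc <- ndisc + 1L
      qsum <- qsum + hm / sh
    }
  }
  c(nret, ndisc, qsum)
}

#' FDRP and qFDRP per CpG with reservoir sampling
#'
#' For each CpG a uniform reservoir of up to `capacity` covering reads is
#' maintained during the sweep.  At flush, all unordered pairs among the
#' sample are formed; pairs sharing fewer than `min_overlap` CpG positions
#' are excluded.  FDRP is the fraction of retained pairs that disagree at
#' >= 1 shared position; qFDRP is the mean normalized Hamming distance
#' (`hamming / shared`) over retained pairs.  The depth column reports the
#' total number of covering reads offered (`seen`), not the sample size.
#'
#' @inheritParams compute_pdr
#' @param capacity Reservoir capacity (default 40; with `capacity >= depth`
#'   the computation is exhaustive and deterministic).
#' @param min_depth Minimum `seen` for a CpG to be reported (default 10).
#' @param min_overlap Minimum shared CpG count for a pair to be retained
#'   (default 1).
#' @param seed Integer seed for the single RNG driving all reservoirs in
#'   sweep order; identical (input, flags, seed) gives identical output.
#'   `NULL` leaves the session RNG untouched.
#' @return List with elements `fdrp` and `qfdrp`, each a record data.table.
#' @export
compute_fdrp_qfdrp <- function(reads, capacity = 40L, min_depth = 10L,
                               min_overlap = 1L, seed = 1L) {
  stopifnot(capacity >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  total_calls <- sum(lengths(reads$pos))
  idx <- new.env(hash = TRUE, parent = emptyenv())
  slots <- vector("list", total_calls)
  seen <- integer(total_calls)
  kchrom <- character(total_calls)
  kpos <- integer(total_calls)
  nk <- 0L
  n <- length(reads$pos)
  for (i in seq_len(n)) {
    ps <- reads$pos[[i]]
    ch <- reads$chrom[i]
    for (p in ps) {
      key <- paste0(ch, ":", p)
      k <- idx[[key]]
      if (is.null(k)) {
        nk <- nk + 1L
        k <- nk
        idx[[key]] <- k
        kchrom[k] <- ch
        kpos[k] <- p
        slots[[k]] <- integer(0)
      }
      s <- seen[k] + 1L
      seen[k] <- s
      if (s <= capacity) {
        slots[[k]][s] <- i
      } else {
        j <- sample.int(s, 1L)
        if (j <= capacity) slots[[k]][j] <- i
      }
    }
  }
  if (nk == 0L) return(list(fdrp = .empty_records(), qfdrp = .empty_records()))
  ord <- order(match(kchrom[seq_len(nk)], unique(reads$chrom)),
               kpos[seq_len(nk)])
  rows <- vector("list", nk)
  nr <- 0L
  for (k in ord) {
    if (seen[k] < min_depth) next
    sm <- slots[[k]]
    if (length(sm) < 2L) next
    ev <- .pairs_eval(reads$pos[sm], reads$meth[sm], min_overlap)
    if (ev[1L] < 1) next
    nr <- nr + 1L
    rows[[nr]] <- list(chrom = kchrom[k], start = kpos[k],
                       fdrp = ev[2L] / ev[1L], qfdrp = ev[3L] / ev[1L],
                       depth = seen[k])
  }
  if (nr == 0L) return(list(fdrp = .empty_records(), qfdrp = .empty_records()))
  out <- rbindlist(lapply(rows[seq_len(nr)], as.data.table))
  list(fdrp = out[, .(chrom, start, end = start + 2L, value = fdrp,
                      depth = as.integer(depth))],
       qfdrp = out[, .(chrom, start, end = start + 2L, value = qfdrp,
                       depth = as.integer(depth))])
}
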