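# Independent CpG-centric oracle. Parses SAM text directly (base-level CIGAR
# expansion, no Rsamtools) and recomputes every measure by gathering, for
# each CpG / quartet / pair, the covering reads from scratch. Deliberately
# naive; used only on small inputs.

oracle_read_sam <- function(path, mapq_min = 10L) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  out <- vector("list", length(body))
  n <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L + 256L + 512L + 1024L + 2048L) != 0L) next
    if (as.integer(f[5L]) < mapq_min) next
    xm <- grep("^XM:Z:", f[-(1:11)], value = TRUE)
    if (!length(xm)) stop("oracle: untagged read ", f[1L])
    xm <- sub("^XM:Z:", "", xm[1L])
    pos0 <- as.integer(f[4L]) - 1L
    toks <- regmatches(f[6L], gregexpr("[0-9]+[MIDNSHP=X]", f[6L]))[[1L]]
    ops <- substring(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    opchars <- rep(ops, lens)
    qcons <- opchars %in% c("M", "I", "S", "=", "X")
    rcons <- opchars %in% c("M", "D", "N", "=", "X")
    refc <- pos0 + cumsum(rcons) - 1L
    ref_per_q <- ifelse(opchars %in% c("M", "=", "X"), refc, NA_integer_)[qcons]
    chars <- strsplit(xm, "")[[1L]]
    stopifnot(length(chars) == sum(qcons))
    z <- chars %in% c("Z", "z")
    p <- ref_per_q[z]
    me <- chars[z] == "Z"
    ok <- !is.na(p)
    p <- p[ok]; me <- me[ok]
    if (!length(p)) next
    if (bitwAnd(flag, 16L) != 0L) p <- p - 1L
    o <- order(p)
    n <- n + 1L
    out[[n]] <- list(chrom = f[3L], pos = p[o], meth = me[o])
  }
  out[seq_len(n)]
}

oracle_cpg_catalog <- function(oreads) {
  if (!length(oreads)) return(data.frame(chrom = character(0), pos = integer(0)))
  levs <- unique(vapply(oreads, `[[`, character(1), "chrom"))
  df <- unique(data.frame(
    chrom = rep(vapply(oreads, `[[`, character(1), "chrom"),
                lengths(lapply(oreads, `[[`, "pos"))),
    pos = unlist(lapply(oreads, `[[`, "pos"))))
  df[order(match(df$chrom, levs), df$pos), , drop = FALSE]
}

oracle_records <- function(chrom, start, end, value, depth) {
  data.table::data.table(chrom = as.character(chrom),
                         start = as.integer(start), end = as.integer(end),
                         value = as.numeric(value), depth = as.integer(depth))
}

oracle_pdr <- function(oreads, min_depth = 10L, min_cpgs = 4L) {
  cat_ <- oracle_cpg_catalog(oreads)
  cls <- lapply(oreads, function(r) {
    if (length(r$pos) < min_cpgs) return(NA)
    any(r$meth) && !all(r$meth)
  })
  rows <- list()
  for (i in seq_len(nrow(cat_))) {
    ch <- cat_$chrom[i]; p <- cat_$pos[i]
    cov <- which(vapply(oreads, function(r)
      r$chrom == ch && p %in% r$pos, logical(1)))
    cov <- cov[!is.na(unlist(cls[cov]))]
    if (length(cov) < min_depth) next
    disc <- unlist(cls[cov])
    rows[[length(rows) + 1L]] <-
      oracle_records(ch, p, p + 2L, sum(disc) / length(disc), length(disc))
  }
  if (!length(rows)) return(oracle_records(character(0), integer(0),
                                           integer(0), numeric(0), integer(0)))
  data.table::rbindlist(rows)
}

oracle_mhl_value <- function(haps) {
  L <- max(lengths(haps))
  num <- numeric(L); tot <- numeric(L)
  for (h in haps) for (i in seq_len(length(h)))
    for (s in seq_len(length(h) - i + 1L)) {
      tot[i] <- tot[i] + 1
      if (all(h[s:(s + i - 1L)])) num[i] <- num[i] + 1
    }
  ok <- tot > 0
  w <- seq_len(L)
  sum(w[ok] * (num[ok] / tot[ok])) / sum(w[ok])
}

oracle_mhl <- function(oreads, min_depth = 10L) {
  cat_ <- oracle_cpg_catalog(oreads)
  rows <- list()
  for (i in seq_len(nrow(cat_))) {
    ch <- cat_$chrom[i]; p <- cat_$pos[i]
    cov <- which(vapply(oreads, function(r)
      r$chrom == ch && p %in% r$pos, logical(1)))
    if (length(cov) < min_depth) next
    rows[[length(rows) + 1L]] <-
      oracle_records(ch, p, p + 2L,
                     oracle_mhl_value(lapply(oreads[cov], `[[`, "meth")),
                     length(cov))
  }
  if (!length(rows)) return(oracle_records(character(0), integer(0),
                                           integer(0), numeric(0), integer(0)))
  data.table::rbindlist(rows)
}

oracle_lpmd <- function(oreads, d_min = 2L, d_max = 16L, min_pair_depth = 4L) {
  cat_ <- oracle_cpg_catalog(oreads)
  tot <- 0L; totd <- 0L
  rows <- list()
  bd_n <- integer(d_max - d_min + 1L)
  bd_d <- integer(d_max - d_min + 1L)
  for (i in seq_len(nrow(cat_))) for (j in seq_len(nrow(cat_))) {
    if (i >= j) next
    if (cat_$chrom[i] != cat_$chrom[j]) next
    dd <- cat_$pos[j] - cat_$pos[i]
    if (dd < d_min || dd > d_max) next
    p1 <- cat_$pos[i]; p2 <- cat_$pos[j]; ch <- cat_$chrom[i]
    nc <- 0L; nd <- 0L
    for (r in oreads) {
      if (r$chrom != ch) next
      a <- match(p1, r$pos); b <- match(p2, r$pos)
      if (is.na(a) || is.na(b)) next
      if (r$meth[a] == r$meth[b]) nc <- nc + 1L else nd <- nd + 1L
    }
    if (nc + nd == 0L) next
    tot <- tot + nc + nd; totd <- totd + nd
    bd_n[dd - d_min + 1L] <- bd_n[dd - d_min + 1L] + nc + nd
    bd_d[dd - d_min + 1L] <- bd_d[dd - d_min + 1L] + nd
    if (nc + nd >= min_pair_depth)
      rows[[length(rows) + 1L]] <-
        oracle_records(ch, p1, p2 + 2L, nd / (nc + nd), nc + nd)
  }
  pairs <- if (length(rows)) data.table::rbindlist(rows)
           else oracle_records(character(0), integer(0), integer(0),
                               numeric(0), integer(0))
  list(global = if (tot > 0L) totd / tot else NA_real_,
       pairs = pairs,
       by_distance = data.table::data.table(
         distance = seq.int(d_min, d_max), n_pairs = bd_n,
         lpmd = ifelse(bd_n > 0L, bd_d / bd_n, NA_real_)))
}

oracle_pm_me <- function(oreads, min_depth = 10L) {
  levs <- unique(vapply(oreads, `[[`, character(1), "chrom"))
  keys <- list()
  for (r in oreads) {
    cc <- length(r$pos)
    if (cc < 4L) next
    for (s in seq_len(cc - 3L))
      keys[[length(keys) + 1L]] <- c(r$chrom, r$pos[s:(s + 3L)])
  }
  if (!length(keys))
    return(list(pm = oracle_records(character(0), integer(0), integer(0),
                                    numeric(0), integer(0)),
                me = oracle_records(character(0), integer(0), integer(0),
                                    numeric(0), integer(0))))
  ukeys <- unique(keys)
  kch <- vapply(ukeys, `[[`, character(1), 1L)
  kp <- vapply(ukeys, function(k) as.integer(k[2:5]), integer(4))
  ord <- order(match(kch, levs), kp[1L, ], kp[2L, ], kp[3L, ], kp[4L, ])
  pm_rows <- list(); me_rows <- list()
  for (k in ukeys[ord]) {
    ch <- k[1L]; kp <- as.integer(k[2:5])
    cnt <- integer(16L)
    for (r in oreads) {
      if (r$chrom != ch) next
      a <- match(kp[1L], r$pos)
      if (is.na(a) || a + 3L > length(r$pos)) next
      if (!all(r$pos[a:(a + 3L)] == kp)) next
      m <- as.integer(r$meth[a:(a + 3L)])
      pat <- m[1L] + 2L * m[2L] + 4L * m[3L] + 8L * m[4L]
      cnt[pat + 1L] <- cnt[pat + 1L] + 1L
    }
    n <- sum(cnt)
    if (n < min_depth) next
    p <- cnt / n
    nz <- p > 0
    pm_rows[[length(pm_rows) + 1L]] <-
      oracle_records(ch, kp[1L], kp[4L] + 2L, 1 - sum(p * p), n)
    me_rows[[length(me_rows) + 1L]] <-
      oracle_records(ch, kp[1L], kp[4L] + 2L,
                     -sum(p[nz] * log2(p[nz])) / 4, n)
  }
  emp <- oracle_records(character(0), integer(0), integer(0), numeric(0),
                        integer(0))
  list(pm = if (length(pm_rows)) data.table::rbindlist(pm_rows) else emp,
       me = if (length(me_rows)) data.table::rbindlist(me_rows) else emp)
}

# exhaustive all-pairs FDRP/qFDRP (the capacity >= depth case)
oracle_fdrp_qfdrp <- function(oreads, min_depth = 10L, min_overlap = 1L) {
  cat_ <- oracle_cpg_catalog(oreads)
  f_rows <- list(); q_rows <- list()
  for (i in seq_len(nrow(cat_))) {
    ch <- cat_$chrom[i]; p <- cat_$pos[i]
    cov <- which(vapply(oreads, function(r)
      r$chrom == ch && p %in% r$pos, logical(1)))
    if (length(cov) < min_depth || length(cov) < 2L) next
    nret <- 0L; ndisc <- 0L; qsum <- 0
    for (a in seq_len(length(cov) - 1L)) for (b in seq.int(a + 1L, length(cov))) {
      ra <- oreads[[cov[a]]]; rb <- oreads[[cov[b]]]
      ia <- match(ra$pos, rb$pos)
      sel <- !is.na(ia)
      sh <- sum(sel)
      if (sh < max(1L, min_overlap)) next
      hm <- sum(ra$meth[sel] != rb$meth[ia[sel]])
      nret <- nret + 1L
      if (hm > 0L) ndisc <- ndisc + 1L
      qsum <- qsum + hm / sh
    }
    if (nret < 1L) next
    f_rows[[length(f_rows) + 1L]] <-
      oracle_records(ch, p, p + 2L, ndisc / nret, length(cov))
    q_rows[[length(q_rows) + 1L]] <-
      oracle_records(ch, p, p + 2L, qsum / nret, length(cov))
  }
  emp <- oracle_records(character(0), integer(0), integer(0), numeric(0),
                        integer(0))
  list(fdrp = if (length(f_rows)) data.table::rbindlist(f_rows) else emp,
       qfdrp = if (length(q_rows)) data.table::rbindlist(q_rows) else emp)
}
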