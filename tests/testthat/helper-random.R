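# Randomized tagged SAM inputs for the equivalence and property sweeps:
# simulator output post-processed at the text level with soft clips,
# insertions, paired flags and junk records both code paths must ignore.

random_locus_set <- function(seed, call_error = 0.05, max_depth = 25L) {
  set.seed(seed)
  configs <- list()
  for (ci in seq_len(sample(1:2, 1L))) {
    base <- 50L
    for (l in seq_len(sample(3:6, 1L))) {
      k <- sample(2:6, 1L)
      gaps <- sample(2:20, k - 1L, replace = TRUE)
      cpg <- as.integer(base + cumsum(c(0L, gaps)))
      probs <- stats::rgamma(2^k, 0.5)
      probs <- probs / sum(probs)
      rl <- sample(c(30L, 40L, 50L), 1L)
      configs[[length(configs) + 1L]] <- locus_config(
        paste0("chr", ci), cpg, probs,
        depth = sample(2:max_depth, 1L), read_length = rl,
        call_error = call_error)
      base <- max(cpg) + rl + sample(10L:60L, 1L)
    }
  }
  configs
}

mutate_sam_text <- function(path, seed) {
  set.seed(seed)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  out <- character(0)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    u <- stats::runif(1)
    qlen <- nchar(f[10L])
    if (u < 0.15) {
      # leading soft clip: consumes query, not reference
      f[6L] <- paste0("2S", f[6L])
      f[10L] <- paste0("AA", f[10L])
      f[11L] <- paste0("II", f[11L])
      f[12L] <- sub("^XM:Z:", "XM:Z:..", f[12L])
    } else if (u < 0.25 && grepl("^[0-9]+M$", f[6L])) {
      # 1 bp insertion after the first aligned base
      n <- as.integer(sub("M$", "", f[6L]))
      f[6L] <- sprintf("1M1I%dM", n - 1L)
      f[10L] <- paste0(substr(f[10L], 1L, 1L), "A", substr(f[10L], 2L, qlen))
      f[11L] <- paste0("I", f[11L])
      xm <- sub("^XM:Z:", "", f[12L])
      f[12L] <- paste0("XM:Z:", substr(xm, 1L, 1L), ".",
                       substr(xm, 2L, qlen))
    }
    if (stats::runif(1) < 0.2)
      f[2L] <- as.character(bitwOr(as.integer(f[2L]), 1L + 64L))
    out <- c(out, paste(f, collapse = "\t"))
    v <- stats::runif(1)
    junk <- NULL
    if (v < 0.05) {
      junk <- f; junk[2L] <- as.character(bitwOr(as.integer(f[2L]), 1024L))
    } else if (v < 0.09) {
      junk <- f; junk[2L] <- as.character(bitwOr(as.integer(f[2L]), 256L))
    } else if (v < 0.13) {
      junk <- f; junk[5L] <- "3"
    }
    if (!is.null(junk)) {
      junk[1L] <- paste0(junk[1L], "_junk")
      out <- c(out, paste(junk, collapse = "\t"))
    }
  }
  writeLines(c(hdr, out), path)
  path
}

random_tagged_sam <- function(seed, path = tempfile(fileext = ".sam")) {
  configs <- random_locus_set(seed)
  simulate_alignments(configs, seed = seed + 1000L, sam_path = path,
                      reverse_fraction = 0.3, compute_truth = FALSE)
  mutate_sam_text(path, seed + 2000L)
}
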