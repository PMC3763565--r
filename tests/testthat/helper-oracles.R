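# Brute-force O(N^2) pair-count oracles, independent of the production
# sliding-window code path.
brute_auto <- function(chroms, W, strands = "both") {
  counts <- numeric(W)
  for (ch in chroms) {
    sets <- if (strands == "both") list(ch$plus, ch$minus) else list(ch$plus)
    for (pos in sets) {
      pos <- sort(unique(as.integer(pos)))
      if (!length(pos)) next
      d <- outer(pos, pos, `-`)
      d <- d[d >= 0 & d < W]
      counts <- counts + tabulate(d + 1L, nbins = W)
    }
  }
  counts
}

brute_cross <- function(chroms, W) {
  counts <- numeric(W)
  for (ch in chroms) {
    p <- sort(unique(as.integer(ch$plus)))
    m <- sort(unique(as.integer(ch$minus)))
    if (!length(p) || !length(m)) next
    d <- outer(p, m, function(a, b) b - a)
    d <- d[d >= 0 & d < W]
    counts <- counts + tabulate(d + 1L, nbins = W)
  }
  counts
}

# quick constructor for in-memory read-start sets
starts_of <- function(plus = integer(0), minus = integer(0), ...,
                      chrom = "chr1") {
  ch <- stats::setNames(list(list(plus = plus, minus = minus)), chrom)
  stranded_read_starts(ch, ...)
}

random_chroms <- function(n, genome = 5000, n_chrom = 2) {
  chroms <- list()
  for (i in seq_len(n_chrom)) {
    chroms[[paste0("chr", i)]] <- list(
      plus = sort(unique(sample.int(genome, n) - 1L)),
      minus = sort(unique(sample.int(genome, n) - 1L)))
  }
  chroms
}
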