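# shared fixture builders; everything is generated in code at test time

gr <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}

# random merged interval set on one toy chromosome (0-based inputs)
randomIntervalSet <- function(n = 8, chromLen = 10000) {
  s <- sort(sample.int(chromLen - 100, n))
  w <- sample(20:500, n, replace = TRUE)
  GenomicRanges::reduce(gr("chr1", s, pmin(s + w, chromLen)))
}

# per-base occupancy vector of a GRanges on chr1 over [0, chromLen)
baseMask <- function(set, chromLen = 10000) {
  v <- logical(chromLen)
  if (length(set)) {
    set <- set[as.character(GenomicRanges::seqnames(set)) == "chr1"]
    for (i in seq_along(set)) {
      a <- GenomicRanges::start(set)[i]
      b <- min(GenomicRanges::end(set)[i], chromLen)
      if (b >= a) v[a:b] <- TRUE
    }
  }
  v
}

# maximal runs of TRUE -> GRanges (brute-force inverse of baseMask)
maskToGRanges <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges("chr1", IRanges::IRanges(starts[keep], ends[keep]))
}

# strongly informative test motif: near-consensus ACGTAC ... of width k
consensusMotif <- function(consensus = "ACGTACGT", soft = 0.02) {
  k <- nchar(consensus)
  m <- matrix(soft, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(k)) m[substr(consensus, j, j), j] <- 1 - 3 * soft
  MotifMatrix(paste0("cons", k), m)
}

# independent combinatorial hypergeometric tail: P(X >= q) by choose() sums
hyperTailOracle <- function(q, K, N, n) {
  kk <- q:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
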