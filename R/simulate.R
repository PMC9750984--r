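#' Simulate a random genome
#'
#' Generates chromosomes of i.i.d. bases at a stated GC content; a pure
#' function of (seed, parameters), so reruns are bit-identical.
#'
#' @param seed integer seed.
#' @param nChrom number of chromosomes (named chr1..chrN).
#' @param chromLen chromosome length(s) in bp (recycled), >= 1000.
#' @param gc GC fraction in the open interval (0, 1).
#' @return named \link[Biostrings]{DNAStringSet}.
#' @export
simulateGenome <- function(seed, nChrom = 1, chromLen = 1e5, gc = 0.5) {
  .assertScalarNumber(gc, "gc", 0, 1, openLower = TRUE, openUpper = TRUE)
  chromLen <- rep_len(chromLen, nChrom)
  if (any(chromLen < 1000))
    stop("chromLen must be >= 1000", call. = FALSE)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(seed, {
    seqs <- vapply(chromLen, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(nChrom))
    out
  })
}

#' Simulate a spike-in (ChIP-Rx) experiment
#'
#' Emulates a two-genome read population: each sample's target-genome IP
#' read count is Poisson with mean \code{depth x occupancy}, its spike-in
#' IP count Poisson with mean \code{depth x spikeFraction} (the fixed
#' exogenous admixture), and its input counts are occupancy-independent
#' (\code{depth} and \code{depth x spikeFraction}).  The true occupancy
#' ratios are recorded as ground truth.
#'
#' @param seed integer seed.
#' @param occupancy named vector of true per-sample global occupancy
#'   ratios (> 0).
#' @param depth expected target-genome reads per sample.
#' @param spikeFraction exogenous admixture fraction (default 0.20).
#' @param emitFragments also emit a fragment-level table (uniform
#'   positions on nominal target/spike-in chromosomes).
#' @param fragLen,targetLen,spikeLen fragment and nominal chromosome sizes
#'   used when emitting fragments.
#' @return list with \code{counts} (a \linkS4class{SpikeInCounts}),
#'   \code{fragments} (GRanges or NULL) and \code{truth} (seed,
#'   parameters, true occupancy).
#' @export
simulateSpikeInExperiment <- function(seed, occupancy, depth = 1e5,
                                      spikeFraction = 0.2,
                                      emitFragments = FALSE,
                                      fragLen = 300, targetLen = 1e6,
                                      spikeLen = 2e5) {
  if (any(occupancy <= 0)) stop("occupancy ratios must be > 0",
                                call. = FALSE)
  if (is.null(names(occupancy)))
    names(occupancy) <- paste0("sample", seq_along(occupancy))
  withSeed(seed, {
    n <- length(occupancy)
    H_IP <- stats::rpois(n, depth * occupancy)
    D_IP <- stats::rpois(n, depth * spikeFraction)
    H_in <- stats::rpois(n, depth)
    D_in <- stats::rpois(n, depth * spikeFraction)
    counts <- SpikeInCounts(H_IP, D_IP, H_in, D_in,
                            samples = names(occupancy))
    frags <- NULL
    if (emitFragments && depth > 0) {
      mk <- function(s, nFrag, genome, role, len) {
        if (nFrag == 0) return(NULL)
        start <- sample.int(max(1, len - fragLen), nFrag, replace = TRUE)
        GenomicRanges::GRanges(
          ifelse(genome == "target", "chrT1", "chrS1"),
          IRanges::IRanges(start, start + fragLen - 1),
          genome = genome, sample = s, role = role)
      }
      pieces <- list()
      for (i in seq_len(n)) {
        s <- names(occupancy)[i]
        pieces <- c(pieces, list(
          mk(s, H_IP[i], "target", "IP", targetLen),
          mk(s, D_IP[i], "spikein", "IP", spikeLen),
          mk(s, H_in[i], "target", "input", targetLen),
          mk(s, D_in[i], "spikein", "input", spikeLen)))
      }
      pieces <- pieces[!vapply(pieces, is.null, logical(1))]
      frags <- if (length(pieces)) suppressWarnings(do.call(c, pieces))
               else GenomicRanges::GRanges()
    }
    list(counts = counts, fragments = frags,
         truth = list(seed = seed, occupancy = occupancy, depth = depth,
                      spikeFraction = spikeFraction))
  })
}

#' Simulate replicate fragment sets with planted differential regions
#'
#' Per non-overlapping window of the grid, each replicate draws a
#' negative-binomial count with the stated base mean and dispersion; for
#' group-2 replicates the mean is multiplied by the planted fold inside
#' each planted region.  Counted fragments are emitted as fixed-length
#' records whose midpoints are uniform within their window, so
#' fragment-level counting reproduces the simulated counts exactly.
#'
#' @param seed integer seed.
#' @param seqlengths named chromosome lengths.
#' @param window window width in bp (windows tile without overlap during
#'   generation).
#' @param groups named integer vector of replicate counts for exactly two
#'   groups, e.g. \code{c(WT = 3, MUT = 3)}.
#' @param baseMean mean fragment count per window.
#' @param dispersion negative-binomial dispersion.
#' @param planted GRanges of planted regions with a numeric \code{fold}
#'   metadata column (> 0); must not overlap one another.
#' @param fragLen emitted fragment length.
#' @return list with \code{fragments} (GRanges, metadata columns
#'   \code{sample}, \code{group}), \code{samples} (sample-to-group map)
#'   and \code{truth} (planted regions, parameters).
#' @export
simulateDifferentialTags <- function(seed, seqlengths, window = 300,
                                     groups = c(g1 = 3, g2 = 3),
                                     baseMean = 50, dispersion = 0.1,
                                     planted = GenomicRanges::GRanges(),
                                     fragLen = 300) {
  if (length(groups) != 2 || is.null(names(groups)))
    stop("groups must be a named vector of two replicate counts",
         call. = FALSE)
  if (length(planted)) {
    if (is.null(planted$fold) || any(planted$fold <= 0))
      stop("planted regions need a positive 'fold' column", call. = FALSE)
    if (!IRanges::isDisjoint(planted))
      stop("planted regions must not overlap", call. = FALSE)
  }
  grid <- tileWindows(seqlengths, window = window, step = window)
  inPlanted <- GenomicRanges::findOverlaps(grid, planted,
                                           ignore.strand = TRUE,
                                           select = "first")
  fold <- rep(1, length(grid))
  hit <- !is.na(inPlanted)
  fold[hit] <- planted$fold[inPlanted[hit]]
  samples <- rep(names(groups), groups)
  samples <- paste0(samples, "_r",
                    unlist(lapply(groups, seq_len), use.names = FALSE))
  groupOf <- rep(names(groups), groups)
  names(groupOf) <- samples
  withSeed(seed, {
    pieces <- list()
    for (i in seq_along(samples)) {
      mu <- if (groupOf[i] == names(groups)[2]) baseMean * fold
            else rep(baseMean, length(grid))
      cnt <- stats::rnbinom(length(grid), size = 1 / dispersion, mu = mu)
      tot <- sum(cnt)
      if (tot == 0) next
      widx <- rep.int(seq_along(grid), cnt)
      mid0 <- (GenomicRanges::start(grid)[widx] - 1) +
        floor(stats::runif(tot) * window)
      half <- floor(fragLen / 2)
      pieces[[i]] <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(grid)[widx],
        IRanges::IRanges(mid0 - half + 1, mid0 - half + fragLen),
        sample = samples[i], group = groupOf[i])
    }
    frags <- if (length(pieces)) do.call(c, pieces[!vapply(pieces, is.null,
                                                           logical(1))])
             else GenomicRanges::GRanges()
    list(fragments = frags, samples = groupOf,
         truth = list(seed = seed, window = window, baseMean = baseMean,
                      dispersion = dispersion, planted = planted,
                      seqlengths = seqlengths))
  })
}

#' Simulate non-overlapping enhancer-like intervals
#'
#' @param seed integer seed.
#' @param seqlengths named chromosome lengths.
#' @param n number of intervals (>= 0).
#' @param widths width distribution: a vector sampled with replacement (a
#'   single value gives fixed-width intervals).
#' @param maxTries placement attempts per interval before giving up.
#' @return sorted, non-overlapping GRanges.
#' @export
simulateEnhancers <- function(seed, seqlengths, n, widths = 500,
                              maxTries = 100) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(GenomicRanges::GRanges())
  withSeed(seed, {
    placed <- GenomicRanges::GRanges()
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        w <- if (length(widths) == 1) widths else sample(widths, 1)
        chr <- sample(names(seqlengths), 1)
        if (seqlengths[[chr]] <= w) next
        st <- sample.int(seqlengths[[chr]] - w, 1)
        cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + w - 1))
        if (!length(placed) ||
            !any(suppressWarnings(IRanges::overlapsAny(cand, placed)))) {
          placed <- suppressWarnings(c(placed, cand))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place ", n, " non-overlapping intervals after ",
             maxTries, " tries each", call. = FALSE)
    }
    GenomicRanges::sort(placed)
  })
}

#' Plant motif instances into sequences
#'
#' Writes the motif consensus (or matrix-sampled instances) at recorded
#' offsets into a seeded subset of the sequences and returns the modified
#' sequences together with the planted-truth table.
#'
#' @param seed integer seed.
#' @param seqs \link[Biostrings]{DNAStringSet}.
#' @param motif a \linkS4class{MotifMatrix}.
#' @param fraction fraction of sequences receiving one instance, in
#'   [0, 1].
#' @param offset fixed 0-based offset, or NULL for a uniform random
#'   offset per sequence.
#' @param sampleFromMatrix draw instance bases from the probability matrix
#'   instead of planting the consensus.
#' @return list with \code{sequences} and \code{truth} (data.frame
#'   \code{seqname}, \code{offset}, \code{instance}).
#' @export
plantMotifs <- function(seed, seqs, motif, fraction = 1, offset = NULL,
                        sampleFromMatrix = FALSE) {
  .assertScalarNumber(fraction, "fraction", 0, 1)
  k <- motifWidth(motif)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  withSeed(seed, {
    nPick <- round(fraction * length(seqs))
    pick <- sort(sample.int(length(seqs), nPick))
    truth <- list()
    out <- as.character(seqs)
    for (i in pick) {
      L <- nchar(out[i])
      if (L < k) {
        warning("sequence ", names(seqs)[i], " shorter than motif; skipped")
        next
      }
      off <- if (is.null(offset)) sample.int(L - k + 1, 1) - 1L
             else as.integer(offset)
      inst <- if (sampleFromMatrix) {
        p <- motifProbs(motif)
        paste(vapply(seq_len(k), function(j)
          sample(rownames(p), 1, prob = p[, j]), character(1)),
          collapse = "")
      } else motifConsensus(motif)
      substr(out[i], off + 1, off + k) <- inst
      truth[[length(truth) + 1]] <- data.frame(
        seqname = names(seqs)[i], offset = off, instance = inst)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seqname = character(), offset = integer(),
                 instance = character())
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(seqs)
    list(sequences = res, truth = truth)
  })
}
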