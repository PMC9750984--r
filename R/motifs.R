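#' Integer-discretised log-odds scoring matrix with exact p-values
#'
#' Converts a position probability matrix to log-odds scores
#' \code{log2((p + pseudocount) / background)}, discretises them onto a
#' uniform grid of \code{gridPoints} units spanning the score range, and
#' precomputes the exact null distribution of the total score of a random
#' background k-mer by dynamic-programming convolution of the per-position
#' score distributions.  Window p-values in \code{\link{scanSequences}} are
#' exact tail probabilities of this distribution at the discretisation
#' grid.
#'
#' @param motif a \linkS4class{MotifMatrix}.
#' @param pseudocount probability pseudocount added before the log.
#' @param gridPoints number of discretisation units across the score range.
#' @return a \linkS4class{PWMScore}.
#' @export
logOdds <- function(motif, pseudocount = 1e-3, gridPoints = 1000) {
  bg <- motif@background
  if (any(bg <= 0)) stop("background frequencies must be > 0",
                         call. = FALSE)
  raw <- log2((motifProbs(motif) + pseudocount) / bg)
  fin <- is.finite(raw)
  if (!any(fin)) stop("degenerate motif: no finite scores", call. = FALSE)
  rng <- max(raw[fin]) - min(raw[fin])
  g <- if (rng > 0) rng / gridPoints else 1
  # zero probability at zero pseudocount: push far below every finite
  # total so such windows can never reach a finite threshold
  raw[!fin] <- min(raw[fin]) - 2 * (rng + g)
  intS <- round(raw / g)
  mode(intS) <- "integer"
  dp <- .scoreTail(intS, bg)
  new("PWMScore", motif = motif, scores = intS, granularity = g,
      tail = dp$tail, minTotal = dp$minTotal)
}

# exact distribution of total integer score of a random background k-mer:
# returns tail[i] = P(total >= minTotal + i - 1)
.scoreTail <- function(intS, bg) {
  dist <- 1
  off <- 0L
  for (j in seq_len(ncol(intS))) {
    s <- intS[, j]
    lo <- min(s)
    newLen <- length(dist) + (max(s) - lo)
    new <- numeric(newLen)
    for (b in 1:4) {
      sh <- s[b] - lo
      new[seq_along(dist) + sh] <- new[seq_along(dist) + sh] +
        bg[b] * dist
    }
    dist <- new
    off <- off + lo
  }
  list(tail = rev(cumsum(rev(dist))), minTotal = off)
}

# P(total >= t) for integer threshold t
.tailAt <- function(tail, minTotal, t) {
  i <- t - minTotal + 1
  ifelse(i <= 1, 1, ifelse(i > length(tail), 0, tail[pmax(i, 1)]))
}

#' Exact p-value of a PWM score threshold
#'
#' Probability that a random background k-mer scores at or above
#' \code{score}, from the precomputed exact distribution.
#'
#' @param pwm a \linkS4class{PWMScore}.
#' @param score threshold in bits (rounded onto the discretisation grid).
#' @return tail probability in [0, 1].
#' @export
scorePvalue <- function(pwm, score) {
  if (is.infinite(score) && score < 0) return(1)
  t <- as.integer(round(score / pwm@granularity))
  unname(.tailAt(pwm@tail, pwm@minTotal, t))
}

# integer window scores of a coded sequence against an integer matrix;
# windows containing non-ACGT bases give NA
.windowScores <- function(code, intS) {
  k <- ncol(intS)
  nW <- length(code) - k + 1
  if (nW < 1) return(numeric(0))
  pos <- outer(seq_len(nW) - 1L, seq_len(k), "+")
  rowSums(matrix(intS[cbind(as.vector(code[pos]),
                            rep(seq_len(k), each = nW))], nW, k))
}

# reverse-complement an integer score matrix (rows A,C,G,T)
.rcScores <- function(intS) {
  intS[4:1, rev(seq_len(ncol(intS))), drop = FALSE]
}

#' Scan sequences for motif occurrences
#'
#' Scores every window of every sequence on both strands and reports
#' windows whose exact background p-value is at most \code{pMax}.  Windows
#' containing non-ACGT characters are skipped; sequences shorter than the
#' motif yield no hits.  Offsets are 0-based window starts on the forward
#' strand.
#'
#' @param seqs a \link[Biostrings]{DNAStringSet} (or named character
#'   vector).
#' @param pwm a \linkS4class{PWMScore} (or a \linkS4class{MotifMatrix},
#'   converted with \code{\link{logOdds}} defaults).
#' @param pMax p-value cutoff.
#' @return data.frame with columns \code{seqname}, \code{offset},
#'   \code{strand}, \code{score} (bits), \code{pvalue}, sorted by
#'   (seqname, offset).
#' @export
scanSequences <- function(seqs, pwm, pMax = 1e-4) {
  if (is(pwm, "MotifMatrix")) pwm <- logOdds(pwm)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  bg <- pwm@motif@background
  rc <- .rcScores(pwm@scores)
  rcDp <- .scoreTail(rc, bg)
  hits <- list()
  for (i in seq_along(seqs)) {
    code <- match(strsplit(as.character(seqs[[i]]), "")[[1]],
                  c("A", "C", "G", "T"))
    for (side in c("+", "-")) {
      sc <- if (side == "+") .windowScores(code, pwm@scores)
            else .windowScores(code, rc)
      if (!length(sc)) next
      p <- if (side == "+") .tailAt(pwm@tail, pwm@minTotal, sc)
           else .tailAt(rcDp$tail, rcDp$minTotal, sc)
      keep <- which(!is.na(sc) & p <= pMax)
      if (length(keep))
        hits[[length(hits) + 1]] <- data.frame(
          seqname = names(seqs)[i], offset = keep - 1L, strand = side,
          score = sc[keep] * pwm@granularity, pvalue = p[keep])
    }
  }
  if (!length(hits))
    return(data.frame(seqname = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$seqname, out$offset, out$strand), , drop = FALSE]
}

#' Extract region sequences from a genome
#'
#' Optionally resizes every region to a fixed width centred on its
#' midpoint (clamped at chromosome ends), then extracts the forward-strand
#' sequence.
#'
#' @param genome named \link[Biostrings]{DNAStringSet} of chromosomes.
#' @param regions GRanges.
#' @param width fixed width in bp, or NULL to extract regions as given.
#' @return \link[Biostrings]{DNAStringSet}, one entry per region.
#' @export
regionSequences <- function(genome, regions, width = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad))
    stop("chromosome(s) absent from genome: ", paste(bad, collapse = ", "),
         call. = FALSE)
  st <- GenomicRanges::start(regions)
  en <- GenomicRanges::end(regions)
  if (!is.null(width)) {
    mid <- floor((st + en) / 2)
    st <- mid - floor(width / 2)
    en <- st + width - 1
    len <- vapply(genome, length, integer(1))[chrom]
    en <- pmin(en, len)
    st <- pmax(1, pmin(st, en - width + 1))
    en <- pmin(len, st + width - 1)
  }
  out <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], st[i], en[i])),
    character(1)))
  names(out) <- sprintf("%s:%d-%d", chrom, st - 1, en)
  out
}

#' Known-motif enrichment in target vs background regions
#'
#' Regions are resized to a fixed width centred on their midpoints, their
#' sequences extracted, and each motif scored under the ZOOPS rule (a
#' sequence counts once if it has at least one hit at \code{pMax}).
#' Over-representation of hit sequences among the targets is tested by a
#' one-sided hypergeometric tail on the pooled target + background
#' universe.
#'
#' @param targets,background GRanges (both non-empty).
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param motifs list of \linkS4class{MotifMatrix} (or a single one).
#' @param pMax per-window hit p-value cutoff.
#' @param width fixed region width in bp.
#' @return data.frame with columns \code{motif}, \code{targetHits},
#'   \code{nTarget}, \code{backgroundHits}, \code{nBackground}, \code{p},
#'   sorted by ascending p (ties by motif name).
#' @export
motifEnrichment <- function(targets, background, genome, motifs,
                            pMax = 1e-4, width = 300) {
  if (length(targets) == 0 || length(background) == 0)
    stop("targets and background must both be non-empty", call. = FALSE)
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  tSeq <- regionSequences(genome, targets, width = width)
  bSeq <- regionSequences(genome, background, width = width)
  names(tSeq) <- paste0("t", seq_along(tSeq))
  names(bSeq) <- paste0("b", seq_along(bSeq))
  rows <- lapply(motifs, function(m) {
    pwm <- logOdds(m)
    tHit <- length(unique(scanSequences(tSeq, pwm, pMax)$seqname))
    bHit <- length(unique(scanSequences(bSeq, pwm, pMax)$seqname))
    data.frame(motif = motifName(m), targetHits = tHit,
               nTarget = length(tSeq), backgroundHits = bHit,
               nBackground = length(bSeq),
               p = hypergeometricEnrichment(tHit, length(tSeq), bHit,
                                            length(bSeq)))
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$motif), , drop = FALSE]
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing at least \code{targetHits} hit sequences among
#' the targets when \code{targetHits + backgroundHits} hit sequences are
#' distributed at random over the pooled target + background universe.
#'
#' @param targetHits,nTarget hit and total counts among targets.
#' @param backgroundHits,nBackground hit and total counts among background.
#' @return p-value in (0, 1].
#' @export
hypergeometricEnrichment <- function(targetHits, nTarget, backgroundHits,
                                     nBackground) {
  K <- targetHits + backgroundHits
  N <- nTarget + nBackground
  stats::phyper(targetHits - 1, K, N - K, nTarget, lower.tail = FALSE)
}

#' Assemble the union-of-top-N motif enrichment heatmap
#'
#' Collects the union of each list's top \code{topN} motifs by ascending
#' enrichment p-value (ties broken by motif name) and fills a motif x list
#' matrix with each list's p-value for each union motif; a motif absent
#' from a list's table is assigned p = 1.  Rows are ordered by the minimum
#' p-value across lists, then name.
#'
#' @param tables named list of enrichment data.frames with columns
#'   \code{motif} and \code{p} (as from \code{\link{motifEnrichment}}).
#' @param topN motifs taken from each list.
#' @return numeric matrix, rows = union motifs, columns = list names.
#' @export
assembleHeatmap <- function(tables, topN = 20) {
  if (!length(tables) || is.null(names(tables)))
    stop("need a named list of enrichment tables", call. = FALSE)
  tops <- lapply(tables, function(tb) {
    tb <- tb[order(tb$p, tb$motif), , drop = FALSE]
    utils::head(tb$motif, topN)
  })
  union <- unique(unlist(tops))
  m <- matrix(1, length(union), length(tables),
              dimnames = list(union, names(tables)))
  for (l in names(tables)) {
    tb <- tables[[l]]
    found <- union[union %in% tb$motif]
    m[found, l] <- tb$p[match(found, tb$motif)]
  }
  m[order(apply(m, 1, min), rownames(m)), , drop = FALSE]
}
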