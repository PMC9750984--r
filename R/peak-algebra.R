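#' Replicate consensus peaks by base-level support
#'
#' Returns the maximal intervals of bases covered by at least \code{k} of
#' the replicate peak sets; with \code{k = 1} this is the merged union,
#' with \code{k = n} the n-way intersection.  Replicate-level peak calls
#' should each be internally merged first.
#'
#' @param replicates list of peak GRanges, one per replicate.
#' @param k minimum replicate support, 1 <= k <= length(replicates).
#' @return GRanges of consensus intervals.
#' @examples
#' reps <- list(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
#'              GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)),
#'              GenomicRanges::GRanges("chr1", IRanges::IRanges(121, 200)))
#' consensusPeaks(reps, k = 2)
#' @export
consensusPeaks <- function(replicates, k) {
  n <- length(replicates)
  if (k < 1 || k > n)
    stop("k must lie in [1, ", n, "]", call. = FALSE)
  merged <- lapply(replicates,
                   function(r) GenomicRanges::reduce(r, ignore.strand = TRUE))
  pooled <- suppressWarnings(do.call(c, unname(merged)))
  if (length(pooled) == 0) return(GenomicRanges::GRanges())
  cov <- GenomicRanges::coverage(pooled)
  gr <- methods::as(IRanges::slice(cov, lower = k, rangesOnly = TRUE),
                    "GRanges")
  GenomicRanges::sort(gr)
}

#' Intersect two merged interval sets, keeping long overlaps only
#'
#' Base-wise intersection of two merged peak sets; intersected pieces are
#' kept only when strictly longer than \code{minLen} bases (an exactly
#' 50-bp piece is dropped at the default).  Commutative and, on merged
#' sets, idempotent.
#'
#' @param a,b merged GRanges.
#' @param minLen minimum overlap length in bp (strict).
#' @return GRanges of retained intersections (subset of both inputs
#'   base-wise).
#' @export
intersectMinOverlap <- function(a, b, minLen = 50) {
  pieces <- GenomicRanges::intersect(GenomicRanges::reduce(a,
                                                           ignore.strand = TRUE),
                                     GenomicRanges::reduce(b,
                                                           ignore.strand = TRUE),
                                     ignore.strand = TRUE)
  pieces[GenomicRanges::width(pieces) > minLen]
}

#' Exclusive differential peaks of one pairwise comparison
#'
#' A differential peak is exclusive to its comparison when it shares no
#' base (one shared base disqualifies) with any differential peak from the
#' other two pairwise comparisons.
#'
#' @param triple named list of three differential peak GRanges, one per
#'   pairwise comparison.
#' @param focal name of the comparison whose exclusive peaks are wanted.
#' @return the subset of \code{triple[[focal]]} overlapping neither other
#'   set.
#' @export
exclusivePeaks <- function(triple, focal) {
  if (length(triple) != 3 || is.null(names(triple)))
    stop("need a named list of three comparisons", call. = FALSE)
  if (!focal %in% names(triple))
    stop("focal comparison '", focal, "' not among: ",
         paste(names(triple), collapse = ", "), call. = FALSE)
  others <- suppressWarnings(
    do.call(c, unname(triple[setdiff(names(triple), focal)])))
  f <- triple[[focal]]
  if (length(others) == 0) return(f)
  f[!IRanges::overlapsAny(f, others, minoverlap = 1,
                          ignore.strand = TRUE)]
}

#' Promoter windows around annotated TSS
#'
#' @param tss data.frame from \code{\link{readTss}} (0-based \code{pos}).
#' @param upstream,downstream extent in bp on either side of the TSS.
#' @return GRanges of promoter windows (one per gene, \code{gene} column).
#' @export
promoterRegions <- function(tss, upstream = 2000, downstream = 2000) {
  p0 <- tss$pos
  lo <- ifelse(tss$strand == "+", p0 - upstream, p0 - downstream)
  hi <- ifelse(tss$strand == "+", p0 + downstream, p0 + upstream)
  GenomicRanges::GRanges(tss$chrom,
                         IRanges::IRanges(pmax(0, lo) + 1, hi),
                         gene = tss$gene)
}

#' Genomic feature distribution of peaks
#'
#' Assigns each peak to exactly one category by its midpoint with
#' precedence promoter > exon > intron > distal and reports category
#' proportions (summing to 1).
#'
#' @param peaks GRanges (non-empty).
#' @param promoters,exons,introns GRanges of annotation spans.
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{proportion}.
#' @export
featureDistribution <- function(peaks, promoters,
                                exons = GenomicRanges::GRanges(),
                                introns = GenomicRanges::GRanges()) {
  if (length(peaks) == 0)
    stop("empty peak set", call. = FALSE)
  mid <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(.midpoint(peaks),
                                                 .midpoint(peaks)))
  inP <- IRanges::overlapsAny(mid, promoters, ignore.strand = TRUE)
  inE <- !inP & IRanges::overlapsAny(mid, exons, ignore.strand = TRUE)
  inI <- !inP & !inE & IRanges::overlapsAny(mid, introns,
                                            ignore.strand = TRUE)
  cat <- rep("distal", length(peaks))
  cat[inI] <- "intron"
  cat[inE] <- "exon"
  cat[inP] <- "promoter"
  lev <- c("promoter", "exon", "intron", "distal")
  n <- vapply(lev, function(l) sum(cat == l), integer(1))
  data.frame(category = lev, count = unname(n),
             proportion = unname(n) / length(peaks))
}

#' Nearest gene for each peak
#'
#' The gene whose TSS minimises the absolute distance to the peak midpoint
#' wins; exact ties go to the lower-coordinate TSS.  The reported distance
#' is signed in gene orientation: positive when the peak lies downstream
#' of the TSS.  Peaks on chromosomes without any TSS are reported
#' unassigned (NA).
#'
#' @param peaks GRanges.
#' @param tss data.frame from \code{\link{readTss}} (0-based \code{pos}).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{gene}, \code{distance}.
#' @export
nearestGene <- function(peaks, tss) {
  mid0 <- .midpoint(peaks) - 1  # 0-based midpoint
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  gene <- rep(NA_character_, length(peaks))
  dist <- rep(NA_real_, length(peaks))
  ord <- order(tss$chrom, tss$pos)
  tss <- tss[ord, , drop = FALSE]
  for (i in seq_along(peaks)) {
    cand <- which(tss$chrom == chrom[i])
    if (!length(cand)) next
    d <- abs(tss$pos[cand] - mid0[i])
    j <- cand[which.min(d)]  # ties: lowest coordinate (pre-sorted)
    gene[i] <- tss$gene[j]
    dist[i] <- if (tss$strand[j] == "+") mid0[i] - tss$pos[j]
               else tss$pos[j] - mid0[i]
  }
  data.frame(chrom = chrom, start = GenomicRanges::start(peaks) - 1,
             end = GenomicRanges::end(peaks), gene = gene,
             distance = dist)
}
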