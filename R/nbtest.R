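#' Method-of-moments negative-binomial dispersion, binned by mean
#'
#' Per window, the within-group sample variance is pooled across the two
#' groups; windows are then grouped into mean bins and a single pooled
#' moment estimate \code{alpha = sum(var - mu) / sum(mu^2)} is computed per
#' bin, which is stable down to two or three replicates per group.
#' Estimates are floored at \code{floor}.
#'
#' @param counts windows x samples count matrix.
#' @param group group label per sample (two levels).
#' @param nbins number of mean bins.
#' @param floor smallest admissible dispersion.
#' @return numeric dispersion per window.
#' @export
estimateDispersion <- function(counts, group, nbins = 20, floor = 1e-4) {
  groups <- unique(group)
  mu <- rowMeans(counts)
  ss <- 0
  df <- 0
  for (g in groups) {
    sub <- counts[, group == g, drop = FALSE]
    if (ncol(sub) > 1) {
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + (ncol(sub) - 1)
    }
  }
  if (df == 0)
    stop("dispersion estimation needs >1 replicate in some group",
         call. = FALSE)
  v <- ss / df
  alpha <- rep(floor, nrow(counts))
  pos <- mu > 0
  if (any(pos)) {
    br <- unique(stats::quantile(mu[pos], probs = seq(0, 1,
                                                      length.out = nbins + 1)))
    binid <- cut(mu[pos], breaks = br, include.lowest = TRUE, labels = FALSE)
    est <- vapply(split(which(pos), binid), function(idx) {
      max(floor, sum(v[idx] - mu[idx]) / sum(mu[idx]^2))
    }, numeric(1))
    alpha[pos] <- est[as.character(binid)]
  }
  alpha
}

# NB log-likelihood of one window row set under per-window mean mu (vector)
.nbLogLik <- function(counts, size, mu) {
  ll <- numeric(nrow(counts))
  for (j in seq_len(ncol(counts))) {
    term <- ifelse(mu > 0,
                   stats::dnbinom(counts[, j], size = size, mu = mu,
                                  log = TRUE),
                   ifelse(counts[, j] == 0, 0, -Inf))
    ll <- ll + term
  }
  ll
}

#' Per-window negative-binomial two-group test
#'
#' For every window the two group means are compared by a likelihood-ratio
#' test of equal negative-binomial means with a shared, moment-estimated
#' dispersion (\code{\link{estimateDispersion}}), referred to a chi-square
#' distribution with one degree of freedom.  Counts are assumed already on
#' a common scale (spike-in downsampling upstream); no further library
#' normalisation is applied.  The fold change is
#' \code{log2((m2 + c) / (m1 + c))} with pseudocount \code{c}.
#'
#' @param wc a \linkS4class{WindowCounts} with exactly two groups.
#' @param pseudocount fold-change pseudocount \code{c}.
#' @param nbins,dispersionFloor passed to \code{\link{estimateDispersion}}.
#' @return GRanges of the windows with metadata columns \code{mean1},
#'   \code{mean2}, \code{totalCount}, \code{dispersion},
#'   \code{log2FoldChange} (group2 over group1, groups in order of first
#'   appearance), \code{pvalue}.  All-zero windows get p = 1 and fold
#'   change 0.
#' @export
nbTest <- function(wc, pseudocount = 1, nbins = 20, dispersionFloor = 1e-4) {
  counts <- SummarizedExperiment::assay(wc, "counts")
  group <- sampleGroups(wc)
  groups <- unique(group)
  if (length(groups) != 2)
    stop("nbTest needs exactly two groups, got ",
         paste(groups, collapse = ", "), call. = FALSE)
  c1 <- counts[, group == groups[1], drop = FALSE]
  c2 <- counts[, group == groups[2], drop = FALSE]
  m1 <- rowMeans(c1)
  m2 <- rowMeans(c2)
  mu0 <- rowMeans(counts)
  alpha <- estimateDispersion(counts, group, nbins = nbins,
                              floor = dispersionFloor)
  size <- 1 / alpha
  llAlt <- .nbLogLik(c1, size, m1) + .nbLogLik(c2, size, m2)
  llNull <- .nbLogLik(counts, size, mu0)
  stat <- pmax(0, 2 * (llAlt - llNull))
  pvalue <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  zero <- mu0 == 0
  pvalue[zero] <- 1
  lfc[zero] <- 0
  out <- SummarizedExperiment::rowRanges(wc)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    mean1 = m1, mean2 = m2, totalCount = rowSums(counts),
    dispersion = alpha, log2FoldChange = lfc, pvalue = pvalue)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; the adjusted value is never
#' below the raw p-value.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Merge significant windows into differential regions
#'
#' BH adjustment is (re)computed at window level, windows passing the
#' threshold are split by fold-change direction, and overlapping or
#' abutting windows of the same direction are merged.  Each region carries
#' the minimum window p-value and adjusted p-value, the count-weighted mean
#' fold change of its windows, its direction and its window support.
#'
#' @param res window-level GRanges from \code{\link{nbTest}}.
#' @param threshold significance threshold in (0, 1), applied strictly
#'   (\code{< threshold}).
#' @param on which column the threshold tests: \code{"padj"} or
#'   \code{"pvalue"}.
#' @return GRanges of differential regions with metadata columns
#'   \code{direction}, \code{log2FoldChange}, \code{pvalue}, \code{padj},
#'   \code{nWindows}.
#' @export
mergeWindows <- function(res, threshold = 0.05, on = c("padj", "pvalue")) {
  on <- match.arg(on)
  .assertScalarNumber(threshold, "threshold", 0, 1, openLower = TRUE,
                      openUpper = TRUE)
  res$padj <- adjustPvalues(res$pvalue)
  crit <- if (on == "padj") res$padj else res$pvalue
  sig <- crit < threshold
  direction <- ifelse(res$log2FoldChange > 0, "up", "down")
  out <- GenomicRanges::GRanges()
  for (d in c("up", "down")) {
    w <- res[sig & direction == d]
    if (length(w) == 0) next
    merged <- GenomicRanges::reduce(w, with.revmap = TRUE,
                                    ignore.strand = TRUE)
    mc <- S4Vectors::DataFrame(
      direction = rep(d, length(merged)),
      log2FoldChange = vapply(merged$revmap, function(i) {
        wt <- w$totalCount[i]
        if (sum(wt) == 0) mean(w$log2FoldChange[i])
        else sum(w$log2FoldChange[i] * wt) / sum(wt)
      }, numeric(1)),
      pvalue = vapply(merged$revmap, function(i) min(w$pvalue[i]),
                      numeric(1)),
      padj = vapply(merged$revmap, function(i) min(w$padj[i]), numeric(1)),
      nWindows = lengths(merged$revmap))
    merged$revmap <- NULL
    S4Vectors::mcols(merged) <- mc
    out <- c(out, merged)
  }
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Filter differential regions
#'
#' Keeps regions with \code{padj} strictly below \code{padjMax} and fold
#' change strictly beyond \code{minLog2FC} in the requested direction.
#'
#' @param regions GRanges from \code{\link{mergeWindows}}.
#' @param padjMax adjusted-p cutoff (strict).
#' @param minLog2FC fold-change cutoff (strict).
#' @param direction \code{"up"} (log2FC > minLog2FC), \code{"down"}
#'   (log2FC < -minLog2FC) or \code{"both"}.
#' @return the retained subset.
#' @export
filterDifferential <- function(regions, padjMax = 0.05, minLog2FC = 0,
                               direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  lfc <- regions$log2FoldChange
  keepDir <- switch(direction,
                    up = lfc > minLog2FC,
                    down = lfc < -minLog2FC,
                    both = abs(lfc) > minLog2FC)
  regions[regions$padj < padjMax & keepDir]
}

#' Windowed differential pipeline presets
#'
#' Runs \code{\link{nbTest}}, \code{\link{mergeWindows}} and
#' \code{\link{filterDifferential}} under one of two preset modes:
#' \code{"marks"} (histone-mark comparisons; windows selected at
#' padj < 0.05) or \code{"ha"} (tagged-histone binding; windows called at
#' raw p < 0.001, regions then filtered at padj < 0.05 and log2FC > 0).
#'
#' @param wc a \linkS4class{WindowCounts}.
#' @param mode \code{"marks"} or \code{"ha"}.
#' @param direction passed to \code{\link{filterDifferential}}.
#' @param ... passed to \code{\link{nbTest}}.
#' @return list with \code{windows} (per-window results), \code{regions}
#'   (all merged regions) and \code{filtered} (regions after the preset
#'   filter).
#' @export
diffWindows <- function(wc, mode = c("marks", "ha"),
                        direction = "up", ...) {
  mode <- match.arg(mode)
  res <- nbTest(wc, ...)
  regions <- if (mode == "marks")
    mergeWindows(res, threshold = 0.05, on = "padj")
  else
    mergeWindows(res, threshold = 0.001, on = "pvalue")
  list(windows = res, regions = regions,
       filtered = filterDifferential(regions, padjMax = 0.05,
                                     minLog2FC = 0,
                                     direction = direction))
}
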