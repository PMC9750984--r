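#' Initial spike-in scaling factors
#'
#' ChIP-Rx scaling: each IP sample receives a factor inversely proportional
#' to its spike-in IP read count, so that after scaling all samples carry
#' the same exogenous signal and endogenous differences become
#' quantitative.  Without input correction the factor is \code{C / D_IP};
#' with correction the IP spike-in fraction is first normalised by the
#' input spike-in fraction, giving
#' \code{C * (H_in / D_in) * (H_IP / D_IP)}, which additionally absorbs
#' sample-specific spike-in admixture measured in the inputs.  The constant
#' \code{C} cancels after max-adjustment.
#'
#' @param counts a \linkS4class{SpikeInCounts}.
#' @param inputCorrect logical; apply the input-fraction correction.
#' @param C positive constant (cosmetic scale of the initial factors).
#' @return named numeric of initial factors, one per sample.
#' @examples
#' sc <- SpikeInCounts(H_IP = c(a = 1, b = 1), D_IP = c(100, 200),
#'                     H_in = c(1, 1), D_in = c(1, 1))
#' initialScalingFactors(sc, C = 100)  # a 1.0, b 0.5
#' @export
initialScalingFactors <- function(counts, inputCorrect = FALSE, C = 1) {
  m <- spikeCounts(counts)
  zero <- rownames(m)[m[, "D_IP"] == 0]
  if (length(zero))
    stop("zero spike-in IP reads for sample(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  if (!inputCorrect)
    return(C / m[, "D_IP"])
  bad <- rownames(m)[m[, "D_in"] == 0 | m[, "H_in"] == 0]
  if (length(bad))
    stop("input correction needs H_in > 0 and D_in > 0; offending ",
         "sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  C * (m[, "H_in"] / m[, "D_in"]) * (m[, "H_IP"] / m[, "D_IP"])
}

#' Max-adjust scaling factors to (0, 1]
#'
#' Divides every initial factor by the group maximum so the largest becomes
#' exactly 1; the adjusted factors are directly usable as downsampling
#' fractions.  Samples must share the same ChIP antibody (the caller's
#' grouping key).  Idempotent: adjusting already-adjusted factors returns
#' them unchanged.
#'
#' @param initial named positive numeric of initial factors.
#' @return a \linkS4class{ScalingFactors}.
#' @examples
#' adjustedFactors(adjustScalingFactors(c(a = .5, b = .25, c = 1.25)))
#' @export
adjustScalingFactors <- function(initial) {
  if (length(initial) == 0) stop("empty scaling-factor group", call. = FALSE)
  if (any(!is.finite(initial) | initial <= 0))
    stop("initial scaling factors must be positive and finite",
         call. = FALSE)
  new("ScalingFactors", initial = initial,
      adjusted = initial / max(initial))
}

#' Compute spike-in scaling factors from counts
#'
#' Convenience wrapper: \code{\link{initialScalingFactors}} followed by
#' \code{\link{adjustScalingFactors}}.
#'
#' @inheritParams initialScalingFactors
#' @return a \linkS4class{ScalingFactors}.
#' @export
scalingFactors <- function(counts, inputCorrect = FALSE) {
  adjustScalingFactors(initialScalingFactors(counts, inputCorrect))
}

#' Seeded Bernoulli downsampling of fragments
#'
#' Each fragment is kept independently with probability \code{fraction}
#' under a seeded generator, mirroring downsampling of scaled BAMs; the
#' same seed and input always give the identical subset.
#'
#' @param frags fragment GRanges.
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return the kept subset of \code{frags}.
#' @export
downsampleFragments <- function(frags, fraction, seed) {
  .assertScalarNumber(fraction, "fraction", 0, 1, openLower = TRUE)
  if (fraction == 1 || length(frags) == 0) return(frags)
  keep <- withSeed(seed, stats::runif(length(frags)) < fraction)
  frags[keep]
}

#' Global histone-mark level of one sample
#'
#' The depth-invariant ratio-of-ratios occupancy estimate
#' \deqn{(H_{IP}/D_{IP}) / (H_{in}/D_{in})}
#' where H and D are target-genome and spike-in read tallies of the IP and
#' input libraries.  Multiplying all four tallies of a sample by a constant
#' leaves the value unchanged.
#'
#' @param counts a \linkS4class{SpikeInCounts}.
#' @return named numeric, one level per sample.
#' @examples
#' globalMarkLevel(SpikeInCounts(H_IP = c(x = 800), D_IP = 200,
#'                               H_in = 500, D_in = 500))  # 4
#' @export
globalMarkLevel <- function(counts) {
  m <- spikeCounts(counts)
  bad <- rownames(m)[m[, "D_IP"] == 0 | m[, "H_in"] == 0 | m[, "D_in"] == 0]
  if (length(bad))
    stop("global level needs D_IP, H_in, D_in > 0; offending sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  (m[, "H_IP"] / m[, "D_IP"]) / (m[, "H_in"] / m[, "D_in"])
}

#' ChIP-qPCR percent input
#'
#' Standard percent-input algebra: the input Ct is first corrected for the
#' input dilution (\code{log2(1/f)} cycles for an input fraction f, default
#' 1 percent), then
#' \deqn{\%input = 100 \cdot 2^{(Ct_{input} - log_2(1/f)) - Ct_{IP}}.}
#'
#' @param ctIP IP Ct value(s).
#' @param ctInput input Ct value(s).
#' @param inputFraction fraction of chromatin used as input, in (0, 1].
#' @return percent enrichment over input.
#' @export
qpcrPercentInput <- function(ctIP, ctInput, inputFraction = 0.01) {
  .assertScalarNumber(inputFraction, "inputFraction", 0, 1, openLower = TRUE)
  if (any(!is.finite(ctIP)) || any(!is.finite(ctInput)))
    stop("Ct values must be finite", call. = FALSE)
  100 * 2^((ctInput - log2(1 / inputFraction)) - ctIP)
}

#' qPCR enrichment normalised to total H3
#'
#' Computes percent input for every (region, sample, antibody) row of a Ct
#' table and divides each mark's percent input by the matching
#' \code{H3total} percent input for the same region and sample, correcting
#' for local nucleosome density.
#'
#' @param ct data.frame with columns \code{region}, \code{sample},
#'   \code{antibody} (the mark name or \code{"H3total"}), \code{ct},
#'   \code{input_ct} and optionally \code{input_fraction} (default 0.01).
#' @return the table with added \code{percent_input} and, for mark rows,
#'   \code{h3_normalised} columns.
#' @export
qpcrEnrichment <- function(ct) {
  need <- c("region", "sample", "antibody", "ct", "input_ct")
  if (!all(need %in% colnames(ct)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  f <- if ("input_fraction" %in% colnames(ct)) ct$input_fraction else
    rep(0.01, nrow(ct))
  if (any(f <= 0 | f > 1))
    stop("input fraction must lie in (0, 1]", call. = FALSE)
  ct$percent_input <- 100 * 2^((ct$input_ct - log2(1 / f)) - ct$ct)
  key <- paste(ct$region, ct$sample)
  h3 <- ct$antibody == "H3total"
  h3pct <- ct$percent_input[h3]
  names(h3pct) <- key[h3]
  mark <- !h3 & ct$antibody != "none"
  missing <- unique(key[mark][!(key[mark] %in% names(h3pct))])
  if (length(missing))
    stop("no H3total row for: ", paste(missing, collapse = "; "),
         call. = FALSE)
  ct$h3_normalised <- NA_real_
  ct$h3_normalised[mark] <- ct$percent_input[mark] / h3pct[key[mark]]
  ct
}
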