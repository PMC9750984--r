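#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpikeInCounts: per-sample read tallies split by genome of origin
#'
#' Holds, for each sample, the number of IP and input reads assigned to the
#' target genome and to the exogenous spike-in genome.  These four tallies
#' drive both the spike-in scaling factors and the depth-invariant global
#' mark level.
#'
#' @slot counts integer matrix, samples x c("H_IP","D_IP","H_in","D_in"):
#'   target-genome IP reads, spike-in IP reads, target-genome input reads,
#'   spike-in input reads.
#' @export
setClass("SpikeInCounts", representation(counts = "matrix"),
  validity = function(object) {
    m <- object@counts
    msg <- character()
    need <- c("H_IP", "D_IP", "H_in", "D_in")
    if (!identical(colnames(m), need))
      msg <- c(msg, paste("columns must be", paste(need, collapse = ", ")))
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "rows must carry unique sample names")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be nonnegative and finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpikeInCounts object
#'
#' @param H_IP,D_IP,H_in,D_in nonnegative per-sample read tallies
#'   (target-genome IP, spike-in IP, target-genome input, spike-in input).
#' @param samples character vector of sample names.
#' @return a \linkS4class{SpikeInCounts}.
#' @examples
#' SpikeInCounts(H_IP = c(a = 800), D_IP = 200, H_in = 500, D_in = 500)
#' @export
SpikeInCounts <- function(H_IP, D_IP, H_in, D_in,
                          samples = names(H_IP)) {
  if (is.null(samples))
    samples <- paste0("sample", seq_along(H_IP))
  m <- cbind(H_IP = as.numeric(H_IP), D_IP = as.numeric(D_IP),
             H_in = as.numeric(H_in), D_in = as.numeric(D_in))
  rownames(m) <- samples
  new("SpikeInCounts", counts = m)
}

#' @describeIn SpikeInCounts sample names
#' @param x a SpikeInCounts object
#' @export
setMethod("sampleNames", "SpikeInCounts", function(x) rownames(x@counts))

#' @describeIn SpikeInCounts the samples x tallies matrix
#' @param object a SpikeInCounts object
#' @export
setMethod("spikeCounts", "SpikeInCounts", function(object) object@counts)

setMethod("show", "SpikeInCounts", function(object) {
  cat("SpikeInCounts with", nrow(object@counts), "sample(s)\n")
  print(object@counts)
})

#' ScalingFactors: initial and max-adjusted spike-in scaling factors
#'
#' The initial factor is computed from spike-in read tallies; the adjusted
#' factor divides every initial factor by the group maximum so the largest
#' becomes exactly 1 and all lie in (0, 1], ready to be used as downsampling
#' fractions.
#'
#' @slot initial named positive numeric, one per sample.
#' @slot adjusted named numeric in (0,1] with max exactly 1.
#' @export
setClass("ScalingFactors",
  representation(initial = "numeric", adjusted = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@initial), names(object@adjusted)))
      msg <- c(msg, "initial and adjusted must share sample names")
    if (any(object@initial <= 0)) msg <- c(msg, "initial factors must be > 0")
    if (length(object@adjusted)) {
      if (any(object@adjusted <= 0 | object@adjusted > 1))
        msg <- c(msg, "adjusted factors must lie in (0, 1]")
      if (max(object@adjusted) != 1)
        msg <- c(msg, "max adjusted factor must be exactly 1")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn ScalingFactors initial (pre-adjustment) factors
#' @param object a ScalingFactors object
#' @export
setMethod("initialFactors", "ScalingFactors", function(object) object@initial)

#' @describeIn ScalingFactors max-adjusted factors in (0,1]
#' @export
setMethod("adjustedFactors", "ScalingFactors", function(object) object@adjusted)

setMethod("show", "ScalingFactors", function(object) {
  cat("ScalingFactors for", length(object@initial), "sample(s)\n")
  print(data.frame(sample = names(object@initial),
                   initial_sf = unname(object@initial),
                   adjusted_sf = unname(object@adjusted),
                   row.names = NULL))
})

#' MotifMatrix: a position probability matrix with background
#'
#' @slot name motif identifier.
#' @slot matrix 4 x width numeric matrix, rows A,C,G,T, columns summing to 1.
#' @slot background named base frequencies (A,C,G,T), strictly positive.
#' @export
setClass("MotifMatrix",
  representation(name = "character", matrix = "matrix",
                 background = "numeric"),
  validity = function(object) {
    msg <- character()
    m <- object@matrix
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      msg <- c(msg, "matrix rows must be A, C, G, T")
    if (any(m < 0)) msg <- c(msg, "probabilities must be nonnegative")
    if (ncol(m) > 0 && any(abs(colSums(m) - 1) > 1e-6))
      msg <- c(msg, "each column must sum to 1 (tolerance 1e-6)")
    bg <- object@background
    if (!identical(names(bg), c("A", "C", "G", "T")) || any(bg <= 0))
      msg <- c(msg, "background must be positive frequencies for A,C,G,T")
    if (length(msg)) msg else TRUE
  })

#' Construct a MotifMatrix
#'
#' @param name motif identifier.
#' @param matrix 4 x width probability matrix (rows A,C,G,T) or its
#'   transpose; rows are reordered/labelled automatically when unlabelled.
#' @param background named frequencies for A,C,G,T (default uniform).
#' @return a \linkS4class{MotifMatrix}.
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1), nrow = 4,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' MotifMatrix("AT", m)
#' @export
MotifMatrix <- function(name, matrix,
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  if (nrow(matrix) != 4 && ncol(matrix) == 4) matrix <- t(matrix)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  new("MotifMatrix", name = name, matrix = matrix,
      background = background[c("A", "C", "G", "T")])
}

#' @describeIn MotifMatrix motif width in bases
#' @param x a MotifMatrix
#' @export
setMethod("motifWidth", "MotifMatrix", function(x) ncol(x@matrix))

#' @describeIn MotifMatrix motif name
#' @export
setMethod("motifName", "MotifMatrix", function(x) x@name)

#' @describeIn MotifMatrix the 4 x width probability matrix
#' @export
setMethod("motifProbs", "MotifMatrix", function(x) x@matrix)

#' @describeIn MotifMatrix consensus string (highest-probability base per
#'   column, ties to the alphabetically first base)
#' @export
setMethod("motifConsensus", "MotifMatrix", function(x) {
  paste(rownames(x@matrix)[apply(x@matrix, 2, which.max)], collapse = "")
})

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix", object@name, "of width", ncol(object@matrix),
      "- consensus", motifConsensus(object), "\n")
})

#' PWMScore: an integer-discretised log-odds scoring matrix
#'
#' Log-odds scores log2((p + pseudocount) / background) are discretised onto
#' a uniform grid so that the exact null distribution of the total score of
#' a random background k-mer can be computed by dynamic programming; the
#' resulting tail probabilities are the per-window p-values used in
#' scanning.
#'
#' @slot motif the source \linkS4class{MotifMatrix}.
#' @slot scores 4 x width integer score matrix.
#' @slot granularity width of one integer score unit (bits).
#' @slot tail numeric vector of P(total >= s) indexed from minimum total.
#' @slot minTotal smallest achievable integer total score.
#' @export
setClass("PWMScore",
  representation(motif = "MotifMatrix", scores = "matrix",
                 granularity = "numeric", tail = "numeric",
                 minTotal = "integer"))

setMethod("show", "PWMScore", function(object) {
  cat("PWMScore for motif", motifName(object@motif),
      "(width", ncol(object@scores), ") granularity",
      signif(object@granularity, 3), "bits/unit\n")
})

#' WindowCounts: sliding-window fragment counts for a two-group comparison
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are genomic windows,
#' whose single assay \code{"counts"} holds nonnegative integer fragment
#' counts, and whose \code{colData} carries the sample-to-group map used by
#' the negative-binomial differential test.
#'
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'counts' is required")
    else if (any(SummarizedExperiment::assay(object, "counts") < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
      msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
  })

#' Construct a WindowCounts object
#'
#' @param counts windows x samples nonnegative integer matrix.
#' @param windows \link[GenomicRanges]{GRanges} of the window spans, one per
#'   row of \code{counts}.
#' @param group factor/character of length \code{ncol(counts)} mapping each
#'   sample to its condition.
#' @return a \linkS4class{WindowCounts}.
#' @export
WindowCounts <- function(counts, windows, group) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = windows,
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(counts)))
  new("WindowCounts", se)
}

#' @describeIn WindowCounts the sample-to-group map
#' @param x a WindowCounts object
#' @export
setMethod("sampleGroups", "WindowCounts",
          function(x) SummarizedExperiment::colData(x)$group)
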