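#' Read a fragment table
#'
#' The fragment table is the package's surrogate for filtered alignments:
#' one row per sequenced fragment with its genomic span, the genome it
#' aligned to (\code{target} or \code{spikein}), its sample and its role
#' (\code{IP} or \code{input}).  Coordinates in the file are 0-based
#' half-open and become 1-based closed in the returned
#' \link[GenomicRanges]{GRanges}.
#'
#' @param path TSV with header columns
#'   \code{chrom,start,end,genome,sample,role}.
#' @return GRanges with metadata columns \code{genome}, \code{sample},
#'   \code{role}.
#' @export
readFragments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "genome", "sample", "role")
  if (!all(need %in% colnames(df)))
    stop("fragment table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges(genome = character(), sample = character(),
                                  role = character()))
  asFragmentTable(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end),
    genome = df$genome, sample = df$sample, role = df$role))
}

#' Validate a GRanges as a fragment table
#'
#' @param frags GRanges with metadata columns \code{genome} (one of
#'   \code{target}, \code{spikein}), \code{sample}, \code{role} (one of
#'   \code{IP}, \code{input}).
#' @return the validated GRanges.
#' @export
asFragmentTable <- function(frags) {
  mc <- S4Vectors::mcols(frags)
  need <- c("genome", "sample", "role")
  if (!all(need %in% colnames(mc)))
    stop("fragments need metadata columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(mc$genome %in% c("target", "spikein")))
    stop("unknown genome label: ",
         paste(unique(setdiff(mc$genome, c("target", "spikein"))),
               collapse = ", "), call. = FALSE)
  if (!all(mc$role %in% c("IP", "input")))
    stop("fragment role must be 'IP' or 'input'", call. = FALSE)
  frags
}

#' Write a fragment table as TSV
#'
#' Inverse of \code{\link{readFragments}} (coordinates written 0-based
#' half-open).
#'
#' @param frags fragment GRanges.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(frags, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(frags)),
                   start = GenomicRanges::start(frags) - 1,
                   end = GenomicRanges::end(frags),
                   genome = frags$genome, sample = frags$sample,
                   role = frags$role)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally fragments by sample, genome and role
#'
#' @param frags fragment GRanges (see \code{\link{readFragments}}).
#' @return data.frame with columns \code{sample}, \code{genome},
#'   \code{role}, \code{n}; row total equals \code{length(frags)}.
#' @export
fragmentTallies <- function(frags) {
  if (length(frags) == 0)
    return(data.frame(sample = character(), genome = character(),
                      role = character(), n = integer()))
  agg <- stats::aggregate(
    list(n = rep.int(1L, length(frags))),
    by = list(sample = frags$sample, genome = frags$genome,
              role = frags$role),
    FUN = sum)
  agg[order(agg$sample, agg$genome, agg$role), , drop = FALSE]
}

#' Collapse a fragment table into SpikeInCounts
#'
#' @param frags fragment GRanges covering both genomes and both roles.
#' @return a \linkS4class{SpikeInCounts} with one row per sample (absent
#'   combinations tally 0).
#' @export
spikeInCountsFromFragments <- function(frags) {
  samples <- sort(unique(frags$sample))
  pick <- function(genome, role) {
    vapply(samples, function(s)
      sum(frags$sample == s & frags$genome == genome & frags$role == role),
      integer(1))
  }
  SpikeInCounts(H_IP = pick("target", "IP"), D_IP = pick("spikein", "IP"),
                H_in = pick("target", "input"),
                D_in = pick("spikein", "input"), samples = samples)
}
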