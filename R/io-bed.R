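#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of \link[GenomicRanges]{GRanges} at this boundary and
#' converted back by \code{\link{writeBed}}, so a read/write round trip is
#' bit-identical on coordinates.  Columns 4-6 become \code{name},
#' \code{score} and the strand; further columns are retained as opaque
#' character metadata columns.
#'
#' @param path BED file (plain text, tab-separated, optional \code{track}/
#'   \code{#} header lines are skipped).
#' @return a \link[GenomicRanges]{GRanges}, in file order; use
#'   \code{\link[GenomicRanges]{sort}} for (chrom, start) order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineNo[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns", call. = FALSE)
  ncolMin <- min(nf)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineNo[bad[1L]],
         ": non-numeric coordinates", call. = FALSE)
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at line ", lineNo[bad[1L]],
         ": require 0 <= start < end", call. = FALSE)
  strand <- "*"
  if (ncolMin >= 6L) {
    strand <- vapply(fields, `[[`, "", 6L)
    strand[strand == "."] <- "*"
    if (!all(strand %in% c("+", "-", "*")))
      stop("invalid strand character in ", path, call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(factor(chrom,
                                      levels = sort(unique(chrom))),
                               IRanges::IRanges(start + 1, end),
                               strand = strand)
  if (ncolMin >= 4L)
    gr$name <- vapply(fields, `[[`, "", 4L)
  if (ncolMin >= 5L)
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (ncolMin > 6L)
    for (j in seq(7L, ncolMin))
      S4Vectors::mcols(gr)[[paste0("extra", j - 6L)]] <-
        vapply(fields, `[[`, "", j)
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3 when the ranges carry neither names, scores nor strand, BED6
#' otherwise (missing name \code{.}, missing score 0, unstranded \code{.}).
#' Coordinates are converted back to 0-based half-open.
#'
#' @param gr a \link[GenomicRanges]{GRanges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  if (length(gr) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  hasName <- "name" %in% colnames(S4Vectors::mcols(gr))
  hasScore <- "score" %in% colnames(S4Vectors::mcols(gr))
  if (hasName || hasScore || any(strand != "*")) {
    name <- if (hasName) gr$name else rep(".", length(gr))
    score <- if (hasScore) gr$score else rep(0, length(gr))
    strand[strand == "*"] <- "."
    out <- paste(chrom, format(start, scientific = FALSE, trim = TRUE),
                 format(end, scientific = FALSE, trim = TRUE),
                 name, score, strand, sep = "\t")
  } else {
    out <- paste(chrom, format(start, scientific = FALSE, trim = TRUE),
                 format(end, scientific = FALSE, trim = TRUE), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with header columns \code{gene},
#' \code{chrom}, \code{pos} (0-based TSS coordinate) and \code{strand}.
#'
#' @param path TSV file.
#' @return data.frame with those four columns; gene ids are checked unique.
#' @export
readTss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos", "strand")
  if (!all(need %in% colnames(df)))
    stop("TSS table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("duplicate gene ids in TSS annotation", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  df[need]
}
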