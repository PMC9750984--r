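#' Build a sliding-window grid
#'
#' Windows of width \code{window} start every \code{step} bases from
#' position 0 of each chromosome; with \code{step < window} the windows
#' overlap (sliding scan), with \code{step == window} they tile without
#' overlap.
#'
#' @param seqlengths named integer vector of chromosome lengths.
#' @param window window width in bp (> 0).
#' @param step distance between window starts, in (0, window]; the
#'   default 100 bp gives the sliding scan, \code{step = window} a
#'   non-overlapping tiling.
#' @return GRanges of window spans; the grid parameters and chromosome
#'   lengths are stored in its \code{metadata}.
#' @export
tileWindows <- function(seqlengths, window = 300, step = min(100, window)) {
  .assertScalarNumber(window, "window", 0, Inf, openLower = TRUE)
  .assertScalarNumber(step, "step", 0, window, openLower = TRUE)
  if (is.null(names(seqlengths)))
    stop("seqlengths must be named by chromosome", call. = FALSE)
  pieces <- lapply(names(seqlengths), function(chr) {
    starts <- seq(0L, max(0L, seqlengths[[chr]] - 1L), by = step)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts + 1,
                                                 starts + window))
  })
  gr <- do.call(c, pieces)
  S4Vectors::metadata(gr) <- list(window = window, step = step,
                                  seqlengths = seqlengths)
  gr
}

#' Resolve reads or fragments to assignment points
#'
#' Stranded entries are treated as single-end reads and extended to
#' \code{fragmentLength} from their 5' end; unstranded entries are treated
#' as complete fragments and used as-is.  Either way the assignment point
#' is the midpoint of the (extended) fragment.
#'
#' @param frags GRanges of reads or fragments.
#' @param fragmentLength extension length in bp for stranded reads.
#' @return width-1 GRanges of assignment points, metadata columns kept.
#' @export
extendFragments <- function(frags, fragmentLength = 300) {
  .assertScalarNumber(fragmentLength, "fragmentLength", 0, Inf,
                      openLower = TRUE)
  if (length(frags) == 0) return(frags)
  str <- as.character(GenomicRanges::strand(frags))
  s0 <- GenomicRanges::start(frags) - 1  # 0-based
  e0 <- GenomicRanges::end(frags)
  half <- floor(fragmentLength / 2)
  mid0 <- ifelse(str == "+", s0 + half,
          ifelse(str == "-", e0 - fragmentLength + half,
                 floor((s0 + e0) / 2)))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(frags),
                                IRanges::IRanges(mid0 + 1, mid0 + 1))
  S4Vectors::mcols(out) <- S4Vectors::mcols(frags)
  out
}

#' Count assignment points per window and sample
#'
#' A point increments every window whose half-open span contains it; with
#' non-overlapping windows each point is counted exactly once.  Points
#' beyond the recorded chromosome length are clamped into the last window
#' with a warning.
#'
#' @param points width-1 GRanges with a \code{sample} metadata column.
#' @param windows grid from \code{\link{tileWindows}}.
#' @param group named group labels (names are sample ids; their order
#'   fixes the column order and hence which group is the reference in
#'   \code{\link{nbTest}}), or an unnamed vector matching alphabetically
#'   sorted samples; when \code{NULL} every sample gets group
#'   \code{"all"}.
#' @return a \linkS4class{WindowCounts}.
#' @export
countWindows <- function(points, windows, group = NULL) {
  samples <- if (!is.null(names(group))) {
    miss <- setdiff(unique(points$sample), names(group))
    if (length(miss))
      stop("sample(s) missing from group map: ",
           paste(miss, collapse = ", "), call. = FALSE)
    names(group)
  } else sort(unique(points$sample))
  if (length(samples) == 0) samples <- "sample"
  sl <- S4Vectors::metadata(windows)$seqlengths
  if (!is.null(sl) && length(points)) {
    lim <- sl[as.character(GenomicRanges::seqnames(points))]
    over <- which(!is.na(lim) & GenomicRanges::start(points) > lim)
    if (length(over)) {
      warning(length(over),
              " point(s) beyond chromosome length; counted in last window")
      GenomicRanges::ranges(points)[over] <-
        IRanges::IRanges(lim[over], lim[over])
    }
  }
  fo <- GenomicRanges::findOverlaps(points, windows, ignore.strand = TRUE)
  sidx <- match(points$sample, samples)[S4Vectors::queryHits(fo)]
  idx <- (sidx - 1L) * length(windows) + S4Vectors::subjectHits(fo)
  counts <- matrix(tabulate(idx, nbins = length(windows) * length(samples)),
                   nrow = length(windows), ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (is.null(group)) {
    group <- rep("all", length(samples))
  } else if (!is.null(names(group))) {
    group <- unname(group[samples])
  }
  WindowCounts(counts, windows, group)
}

#' Per-base coverage track of one (scaled) sample
#'
#' Scaling is applied by seeded Bernoulli downsampling with the adjusted
#' spike-in factor before computing coverage; track values themselves are
#' never multiplied, so scaling is applied exactly once.
#'
#' @param frags fragment GRanges of a single sample.
#' @param adjustedSf downsampling fraction in (0, 1].
#' @param seed seed for the downsampling draw.
#' @param seqlengths optional named chromosome lengths fixing track widths.
#' @return an \link[IRanges]{RleList} of per-base coverage; the sum over
#'   all bases equals the total covered base-pairs of the kept fragments.
#' @export
coverageTrack <- function(frags, adjustedSf = 1, seed = 1L,
                          seqlengths = NULL) {
  kept <- downsampleFragments(frags, adjustedSf, seed)
  if (length(kept) == 0 && is.null(seqlengths))
    return(IRanges::RleList(compress = TRUE))
  if (is.null(seqlengths)) {
    GenomicRanges::coverage(kept)
  } else {
    chroms <- names(seqlengths)
    covs <- lapply(chroms, function(chr) {
      k <- kept[as.character(GenomicRanges::seqnames(kept)) == chr]
      IRanges::coverage(IRanges::ranges(k), width = seqlengths[[chr]])
    })
    names(covs) <- chroms
    methods::as(covs, "SimpleRleList")
  }
}

#' Write a coverage track as bedGraph
#'
#' With \code{bin = 1} emits one line per constant-coverage run; with a
#' larger bin emits per-bin mean coverage.  Zero-valued stretches are
#' omitted.  Coordinates are 0-based half-open.
#'
#' @param cov RleList from \code{\link{coverageTrack}}.
#' @param path output file.
#' @param bin bin width in bp (>= 1).
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(cov, path, bin = 1) {
  .assertScalarNumber(bin, "bin", 1, Inf)
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(cov)) {
    r <- cov[[chr]]
    if (bin == 1) {
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- c(0, ends[-length(ends)])
      vals <- S4Vectors::runValue(r)
    } else {
      n <- ceiling(length(r) / bin)
      v <- c(as.numeric(r), rep(0, n * bin - length(r)))
      vals <- colMeans(matrix(v, nrow = bin))
      starts <- (seq_len(n) - 1) * bin
      ends <- pmin(starts + bin, length(r))
    }
    keep <- vals != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, as.integer(starts[keep]),
                         as.integer(ends[keep]), vals[keep]), con)
  }
  invisible(path)
}

#' Strand-aware TSS tag-density profile
#'
#' Extracts the coverage in \code{[pos - flank, pos + flank)} around every
#' TSS, averages it in fixed-width bins and orients minus-strand rows so
#' that upstream is always left.  TSS whose flank is truncated by a
#' chromosome end yield all-missing rows and are excluded from the mean
#' profile.
#'
#' @param cov RleList per-base coverage track.
#' @param tss data.frame from \code{\link{readTss}} (0-based \code{pos}).
#' @param flank half-width in bp; must be a multiple of \code{bin}.
#' @param bin bin width in bp.
#' @return list with \code{profile} (TSS x bin matrix, rownames gene ids)
#'   and \code{mean} (column means over complete rows).
#' @export
tssProfile <- function(cov, tss, flank = 2000, bin = 10) {
  if (flank %% bin != 0)
    stop("flank must be a multiple of bin", call. = FALSE)
  nbin <- 2 * flank / bin
  prof <- matrix(NA_real_, nrow(tss), nbin,
                 dimnames = list(tss$gene, NULL))
  for (i in seq_len(nrow(tss))) {
    chr <- tss$chrom[i]
    if (!chr %in% names(cov)) next
    lo <- tss$pos[i] - flank       # 0-based window [lo, hi)
    hi <- tss$pos[i] + flank
    if (lo < 0 || hi > length(cov[[chr]])) next
    v <- as.numeric(cov[[chr]][(lo + 1):hi])
    if (tss$strand[i] == "-") v <- rev(v)
    prof[i, ] <- colMeans(matrix(v, nrow = bin))
  }
  ok <- stats::complete.cases(prof)
  list(profile = prof,
       mean = if (any(ok)) colMeans(prof[ok, , drop = FALSE])
              else rep(NA_real_, nbin))
}
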