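test_that("fragment extension is strand-aware and midpoint-resolved", {
  plus <- gr("chr1", 10, 50, strand = "+")
  p <- extendFragments(plus, 300)
  expect_equal(GenomicRanges::start(p) - 1, 160)  # 10 + 300/2

  minus <- gr("chr1", 400, 500, strand = "-")
  m <- extendFragments(minus, 300)
  expect_equal(GenomicRanges::start(m) - 1, 350)  # 500 - 300 + 150

  paired <- gr("chr1", 100, 401)
  q <- extendFragments(paired, 300)
  expect_equal(GenomicRanges::start(q) - 1, floor((100 + 401) / 2))
})

test_that("window counting covers sliding windows and conserves points", {
  grid <- tileWindows(c(chr1 = 3000), window = 300, step = 100)
  # no points -> all-zero matrix
  pts0 <- GenomicRanges::GRanges()
  pts0$sample <- character()
  wc0 <- countWindows(pts0, grid)
  expect_true(all(SummarizedExperiment::assay(wc0) == 0))

  pt <- gr("chr1", 160, 161)
  pt$sample <- "s1"
  wc <- countWindows(pt, grid)
  cnt <- SummarizedExperiment::assay(wc)
  hitWin <- which(cnt[, 1] > 0)
  expect_equal(GenomicRanges::start(grid)[hitWin] - 1, c(0, 100))

  # non-overlapping tiling counts each point exactly once
  grid1 <- tileWindows(c(chr1 = 300000), window = 300, step = 300)
  set.seed(5)
  pos <- sample.int(299000, 1000)
  pts <- gr("chr1", pos, pos + 1)
  pts$sample <- "s1"
  expect_equal(sum(SummarizedExperiment::assay(countWindows(pts, grid1))),
               1000)

  # point beyond chromosome length lands in the last window with a warning
  far <- gr("chr1", 5000, 5001)
  far$sample <- "s1"
  expect_warning(wcf <- countWindows(far, grid), "beyond chromosome")
  expect_equal(sum(SummarizedExperiment::assay(wcf)), 3)  # last 3 sliders
})

test_that("the NB window test returns nulls for identical or empty data", {
  counts <- cbind(a1 = c(5, 0, 9), a2 = c(7, 0, 9), b1 = c(5, 0, 9),
                  b2 = c(7, 0, 9))
  win <- gr("chr1", c(0, 300, 600), c(300, 600, 900))
  wc <- WindowCounts(counts, win, group = c("g1", "g1", "g2", "g2"))
  res <- nbTest(wc)
  expect_equal(res$log2FoldChange, c(0, 0, 0))
  expect_equal(res$pvalue, c(1, 1, 1))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustPvalues(0.37), 0.37)
  expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")
  p <- runif(100)
  expect_true(all(adjustPvalues(p) >= p))
})

test_that("window merging unions same-direction runs and splits directions", {
  win <- gr("chr1", c(0, 100, 1000, 1300), c(300, 400, 1300, 1600))
  res <- win
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    mean1 = c(10, 10, 10, 10), mean2 = c(90, 80, 1, 90),
    totalCount = c(100, 90, 11, 100), dispersion = 0.1,
    log2FoldChange = c(3, 2.9, -3, 3),
    pvalue = c(1e-9, 1e-8, 1e-9, 1e-9))
  out <- mergeWindows(res, threshold = 0.05)
  # [0,300)+[100,400) same direction -> one region [0,400)
  up <- out[out$direction == "up"]
  expect_equal(GenomicRanges::start(up)[1] - 1, 0)
  expect_equal(GenomicRanges::end(up)[1], 400)
  # abutting opposite-direction windows stay separate regions
  expect_equal(length(out), 3L)
  expect_setequal(out$direction, c("up", "down", "up"))
  # per-direction disjointness, each region holds >= 1 window
  for (d in c("up", "down")) {
    sub <- out[out$direction == d]
    expect_true(IRanges::isDisjoint(sub))
    expect_true(all(sub$nWindows >= 1))
  }
  # region stats: min p and count-weighted mean lfc
  expect_equal(up$pvalue[1], 1e-9)
  expect_equal(up$log2FoldChange[1], (3 * 100 + 2.9 * 90) / 190)
})

test_that("differential filtering applies strict cutoffs per direction", {
  regs <- gr("chr1", c(0, 500, 1000), c(300, 800, 1300))
  S4Vectors::mcols(regs) <- S4Vectors::DataFrame(
    direction = c("up", "up", "down"),
    log2FoldChange = c(1.2, 1.2, -1.0),
    pvalue = c(0.001, 0.02, 0.001),
    padj = c(0.01, 0.05, 0.01), nWindows = 1L)
  kept <- filterDifferential(regs, padjMax = 0.05, minLog2FC = 0,
                             direction = "up")
  expect_length(kept, 1)                       # padj 0.05 dropped (strict)
  expect_equal(kept$log2FoldChange, 1.2)
  expect_length(filterDifferential(regs, direction = "down"), 1)
  expect_length(filterDifferential(regs, direction = "both"), 2)
})

test_that("coverage tracks conserve base coverage and bin correctly", {
  one <- gr("chr1", 10, 20)
  cov <- coverageTrack(one, seqlengths = c(chr1 = 100))
  v <- as.numeric(cov$chr1)
  expect_equal(sum(v), 10)                 # ten covered bases
  expect_true(all(v[11:20] == 1))
  two <- c(gr("chr1", 10, 20), gr("chr1", 15, 25))
  v2 <- as.numeric(coverageTrack(two, seqlengths = c(chr1 = 100))$chr1)
  expect_equal(max(v2), 2)
  expect_equal(sum(v2), 20)
  expect_length(coverageTrack(GenomicRanges::GRanges()), 0)

  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeBedGraph(cov, f)
  parts <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(parts, c("chr1", "10", "20", "1"))
})

test_that("TSS profiles are strand-oriented and exclude truncated rows", {
  # uniform coverage -> flat profile at v
  covU <- IRanges::RleList(chr1 = S4Vectors::Rle(3, 5000))
  tss <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    pos = c(2500, 2600), strand = c("+", "-"))
  pr <- tssProfile(covU, tss, flank = 500, bin = 10)
  expect_true(all(pr$profile == 3))
  expect_equal(pr$mean, rep(3, 100))

  # asymmetric signal: peak upstream of a plus TSS appears mirrored for minus
  vals <- numeric(5000)
  vals[2001:2100] <- 7  # 0-based [2000,2100), upstream of pos 2500
  covA <- IRanges::RleList(chr1 = S4Vectors::Rle(vals))
  one <- data.frame(gene = "g", chrom = "chr1", pos = 2500, strand = "+")
  oneM <- data.frame(gene = "g", chrom = "chr1", pos = 2500, strand = "-")
  pP <- tssProfile(covA, one, flank = 500, bin = 10)$profile[1, ]
  pM <- tssProfile(covA, oneM, flank = 500, bin = 10)$profile[1, ]
  expect_equal(unname(pM), unname(rev(pP)))

  # truncated flank -> NA row, dropped from the mean
  edge <- data.frame(gene = c("in", "out"), chrom = "chr1",
                     pos = c(2500, 100), strand = "+")
  pr2 <- tssProfile(covU, edge, flank = 500, bin = 10)
  expect_true(all(is.na(pr2$profile["out", ])))
  expect_equal(pr2$mean, rep(3, 100))
})
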