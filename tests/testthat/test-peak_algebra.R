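test_that("consensus peaks are the bases covered by >= k replicates", {
  reps <- list(gr("chr1", 0, 100), gr("chr1", 50, 150), gr("chr1", 120, 200))
  cons <- consensusPeaks(reps, k = 2)
  expect_equal(GenomicRanges::start(cons) - 1, c(50, 120))
  expect_equal(GenomicRanges::end(cons), c(100, 150))

  same <- list(gr("chr1", 0, 100), gr("chr1", 0, 100), gr("chr1", 0, 100))
  for (k in 1:3)
    expect_equal(GenomicRanges::ranges(consensusPeaks(same, k)),
                 GenomicRanges::ranges(same[[1]]))

  expect_error(consensusPeaks(reps, 4), "k must lie")
  expect_error(consensusPeaks(reps, 0), "k must lie")
})

test_that("consensus/intersect/exclusive match a per-base oracle", {
  set.seed(77)
  okCons <- okAnti <- okUnion <- okInter <- okMin <- okExc <- TRUE
  for (i in 1:150) {
    reps <- lapply(1:3, function(j) randomIntervalSet(sample(3:10, 1)))
    masks <- lapply(reps, baseMask)
    covSum <- Reduce(`+`, lapply(masks, as.integer))
    for (k in 1:3)
      okCons <- okCons &&
        identical(baseMask(consensusPeaks(reps, k)), covSum >= k)
    # antitone in k; k=1 union, k=3 intersection
    widths <- vapply(1:3, function(k)
      sum(GenomicRanges::width(consensusPeaks(reps, k))), numeric(1))
    okAnti <- okAnti && all(diff(widths) <= 0)
    okUnion <- okUnion && identical(baseMask(consensusPeaks(reps, 1)),
                                    masks[[1]] | masks[[2]] | masks[[3]])
    okInter <- okInter && identical(baseMask(consensusPeaks(reps, 3)),
                                    masks[[1]] & masks[[2]] & masks[[3]])

    # min-overlap intersection vs oracle: pieces > 50 bp of the AND mask
    a <- reps[[1]]; b <- reps[[2]]
    want <- maskToGRanges(masks[[1]] & masks[[2]])
    want <- want[GenomicRanges::width(want) > 50]
    okMin <- okMin && identical(baseMask(intersectMinOverlap(a, b, 50)),
                                baseMask(want))

    # exclusive peaks vs oracle: members of a hitting no base of b or c
    triple <- list(A = reps[[1]], B = reps[[2]], C = reps[[3]])
    otherMask <- masks[[2]] | masks[[3]]
    keep <- vapply(seq_along(a), function(j)
      !any(otherMask[GenomicRanges::start(a)[j]:GenomicRanges::end(a)[j]]),
      logical(1))
    okExc <- okExc && identical(baseMask(exclusivePeaks(triple, "A")),
                                baseMask(a[keep]))
  }
  expect_true(okCons)
  expect_true(okAnti)
  expect_true(okUnion)
  expect_true(okInter)
  expect_true(okMin)
  expect_true(okExc)
})

test_that("min-overlap intersection enforces the strict 50-bp boundary", {
  expect_length(intersectMinOverlap(gr("chr1", 0, 100),
                                    gr("chr1", 51, 150)), 0)   # 49 bp
  expect_length(intersectMinOverlap(gr("chr1", 0, 100),
                                    gr("chr1", 50, 150)), 0)   # exactly 50
  kept <- intersectMinOverlap(gr("chr1", 0, 100), gr("chr1", 49, 150))
  expect_equal(GenomicRanges::width(kept), 51)                 # 51 bp kept
  k60 <- intersectMinOverlap(gr("chr1", 0, 100), gr("chr1", 40, 200))
  expect_equal(GenomicRanges::start(k60) - 1, 40)
  expect_equal(GenomicRanges::end(k60), 100)

  # commutative and idempotent on merged sets
  a <- GenomicRanges::reduce(gr("chr1", c(0, 300), c(200, 600)))
  b <- GenomicRanges::reduce(gr("chr1", c(100, 350), c(250, 700)))
  ab <- intersectMinOverlap(a, b)
  ba <- intersectMinOverlap(b, a)
  expect_equal(GenomicRanges::ranges(ab), GenomicRanges::ranges(ba))
  aa <- intersectMinOverlap(a, a)
  expect_equal(GenomicRanges::ranges(aa),
               GenomicRanges::ranges(a[GenomicRanges::width(a) > 50]))
})

test_that("exclusive peaks reject any single-base overlap", {
  triple <- list(f = gr("chr1", 0, 100), g = gr("chr1", 99, 120),
                 h = GenomicRanges::GRanges())
  expect_length(exclusivePeaks(triple, "f"), 0)  # 1 bp overlap disqualifies

  triple2 <- list(f = c(gr("chr1", 0, 100), gr("chr1", 500, 600)),
                  g = gr("chr1", 90, 120), h = GenomicRanges::GRanges())
  exc <- exclusivePeaks(triple2, "f")
  expect_equal(GenomicRanges::start(exc) - 1, 500)

  empt <- list(f = gr("chr1", 0, 100), g = GenomicRanges::GRanges(),
               h = GenomicRanges::GRanges())
  expect_equal(GenomicRanges::ranges(exclusivePeaks(empt, "f")),
               GenomicRanges::ranges(empt$f))
  expect_error(exclusivePeaks(triple, "nope"), "not among")
})

test_that("feature distribution assigns one category by midpoint", {
  tss <- data.frame(gene = "g1", chrom = "chr1", pos = 10000, strand = "+")
  prom <- promoterRegions(tss)            # [8000, 12000] around the TSS
  exons <- gr("chr1", 20000, 21000)
  introns <- gr("chr1", 21000, 30000)
  peaks <- c(gr("chr1", 9500, 9900),       # promoter
             gr("chr1", 20100, 20300),     # exon
             gr("chr1", 25000, 25400),     # intron
             gr("chr1", 50000, 50200))     # distal
  fd <- featureDistribution(peaks, prom, exons, introns)
  expect_equal(fd$proportion, rep(0.25, 4))
  expect_equal(sum(fd$proportion), 1, tolerance = 1e-12)

  allProm <- featureDistribution(gr("chr1", c(9000, 9500), c(9300, 9800)),
                                 prom, exons, introns)
  expect_equal(allProm$proportion[allProm$category == "promoter"], 1)
  expect_error(featureDistribution(GenomicRanges::GRanges(), prom),
               "empty peak set")
})

test_that("nearest gene minimises TSS distance with a stable tie-break", {
  tss <- data.frame(gene = c("near", "far"), chrom = "chr1",
                    pos = c(100, 2000), strand = c("+", "+"))
  hit <- nearestGene(gr("chr1", 50, 151), tss)  # midpoint 100
  expect_equal(hit$gene, "near")
  expect_equal(hit$distance, 0)

  mid <- nearestGene(gr("chr1", 400, 601), tss)  # midpoint 500
  expect_equal(mid$gene, "near")
  expect_equal(abs(mid$distance), 400)

  # exact tie -> lower-coordinate TSS; minus-strand distance is flipped
  tie <- data.frame(gene = c("b", "a"), chrom = "chr1",
                    pos = c(600, 400), strand = c("-", "+"))
  t1 <- nearestGene(gr("chr1", 450, 551), tie)   # midpoint 500
  expect_equal(t1$gene, "a")
  expect_equal(t1$distance, 100)
  onlyMinus <- data.frame(gene = "m", chrom = "chr1", pos = 600,
                          strand = "-")
  t2 <- nearestGene(gr("chr1", 450, 551), onlyMinus)
  expect_equal(t2$distance, 100)  # 100 bp downstream in gene orientation

  noTss <- nearestGene(gr("chr2", 0, 100), tss)
  expect_true(is.na(noTss$gene))
})
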