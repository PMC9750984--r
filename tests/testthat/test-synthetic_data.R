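test_that("genome simulation honours GC content and determinism", {
  g <- simulateGenome(5, 1, 1e5, gc = 0.5)
  freq <- Biostrings::alphabetFrequency(g[[1]])[c("C", "G")]
  expect_equal(sum(freq) / 1e5, 0.5, tolerance = 0.02)  # binomial bound

  expect_identical(as.character(simulateGenome(5, 2, 2000, .4)),
                   as.character(simulateGenome(5, 2, 2000, .4)))
  expect_error(simulateGenome(1, 1, 1e4, gc = 1.0), "outside the allowed")
  expect_error(simulateGenome(1, 1, 1e4, gc = 0), "outside the allowed")
  expect_error(simulateGenome(1, 1, 500), ">= 1000")
})

test_that("spike-in simulation reflects occupancy in target IP reads", {
  sim <- simulateSpikeInExperiment(23, c(a = 1, b = 0.5), depth = 1e5)
  m <- spikeCounts(sim$counts)
  ratio <- m["a", "H_IP"] / m["b", "H_IP"]
  # Poisson 4-sigma bound around 2:1
  se <- 2 * sqrt(1 / m["a", "H_IP"] + 1 / m["b", "H_IP"])
  expect_lt(abs(ratio - 2), 4 * se * 2)
  expect_equal(sim$truth$occupancy, c(a = 1, b = 0.5))

  zero <- simulateSpikeInExperiment(1, c(a = 1), depth = 0,
                                    emitFragments = TRUE)
  expect_equal(sum(spikeCounts(zero$counts)), 0)
  expect_length(zero$fragments, 0)

  withFrags <- simulateSpikeInExperiment(9, c(a = 1), depth = 1000,
                                         emitFragments = TRUE)
  tal <- fragmentTallies(withFrags$fragments)
  expect_equal(sum(tal$n), sum(spikeCounts(withFrags$counts)))
  rerun <- simulateSpikeInExperiment(9, c(a = 1), depth = 1000,
                                     emitFragments = TRUE)
  expect_identical(GenomicRanges::start(withFrags$fragments),
                   GenomicRanges::start(rerun$fragments))
})

test_that("differential-tag simulation plants folds where stated", {
  sl <- c(chr1 = 3e5)
  pl <- gr("chr1", 60000, 63000)
  pl$fold <- 4
  sim <- simulateDifferentialTags(3, sl, window = 300,
                                  groups = c(wt = 3, mut = 3),
                                  baseMean = 50, dispersion = 0.1,
                                  planted = pl)
  expect_setequal(unique(sim$fragments$group), c("wt", "mut"))
  # counts inside the planted region scale ~4x in the second group
  inside <- IRanges::overlapsAny(sim$fragments, pl)
  nIn <- tapply(inside, sim$fragments$group, sum)
  expect_gt(nIn[["mut"]] / nIn[["wt"]], 2.5)

  rerun <- simulateDifferentialTags(3, sl, window = 300,
                                    groups = c(wt = 3, mut = 3),
                                    baseMean = 50, dispersion = 0.1,
                                    planted = pl)
  expect_identical(GenomicRanges::start(sim$fragments),
                   GenomicRanges::start(rerun$fragments))

  bad <- c(pl, gr("chr1", 61000, 61500))
  bad$fold <- 4
  expect_error(simulateDifferentialTags(1, sl, planted = bad),
               "must not overlap")
  noFold <- gr("chr1", 0, 300)
  expect_error(simulateDifferentialTags(1, sl, planted = noFold),
               "fold")
})

test_that("a fold-1 planted region behaves like background", {
  sl <- c(chr1 = 6e5)
  pl <- gr("chr1", 90000, 93000)
  pl$fold <- 1
  sim <- simulateDifferentialTags(17, sl, window = 300,
                                  groups = c(a = 3, b = 3),
                                  planted = pl)
  wc <- countWindows(extendFragments(sim$fragments, 300),
                     tileWindows(sl, 300, 300), group = sim$samples)
  res <- nbTest(wc)
  hit <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(wc), pl)
  expect_true(all(res$pvalue[hit] > 0.001))  # indistinguishable from null
})

test_that("enhancer simulation places non-overlapping sorted intervals", {
  expect_length(simulateEnhancers(1, c(chr1 = 1e5), 0), 0)
  enh <- simulateEnhancers(21, c(chr1 = 2e5, chr2 = 1e5), 50, widths = 500)
  expect_length(enh, 50)
  expect_true(all(GenomicRanges::width(enh) == 500))
  expect_true(IRanges::isDisjoint(enh))
  expect_false(GenomicRanges::is.unsorted(enh, ignore.strand = TRUE))
  expect_identical(
    GenomicRanges::start(simulateEnhancers(21, c(chr1 = 2e5, chr2 = 1e5),
                                           50, widths = 500)),
    GenomicRanges::start(enh))
  expect_error(simulateEnhancers(1, c(chr1 = 2000), 10, widths = 1900),
               "could not place")
})

test_that("motif planting records truth and respects the fraction", {
  motif <- consensusMotif("ACGTACGT")
  g <- simulateGenome(3, 1, 1000, .5)
  seqs <- Biostrings::DNAStringSet(
    vapply(0:9, function(i)
      substr(as.character(g[[1]]), 1 + 100 * i, 100 * (i + 1)),
      character(1)))
  names(seqs) <- paste0("s", 1:10)

  all37 <- plantMotifs(4, seqs, motif, fraction = 1, offset = 37)
  expect_equal(nrow(all37$truth), 10)
  expect_true(all(all37$truth$offset == 37))
  expect_true(all(vapply(seq_len(10), function(i)
    substr(as.character(all37$sequences[[i]]), 38, 45) == "ACGTACGT",
    logical(1))))

  none <- plantMotifs(4, seqs, motif, fraction = 0)
  expect_identical(as.character(none$sequences), as.character(seqs))
  expect_equal(nrow(none$truth), 0)

  short <- Biostrings::DNAStringSet(c(tiny = "ACG"))
  expect_warning(plantMotifs(1, short, motif, fraction = 1),
                 "shorter than motif")
})

test_that("truth records serialise to JSON including interval components", {
  pl <- gr("chr1", 100, 400)
  pl$fold <- 4
  f <- withr::local_tempfile(fileext = ".json")
  writeTruth(list(seed = 7, planted = pl, baseMean = 50), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$seed, 7)
  expect_equal(back$planted$start, 100)
  expect_equal(back$planted$fold, 4)
})
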