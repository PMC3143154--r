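test_that("binReads places boundary reads in the right bins and conserves reads", {
  # 0-based positions 0, 299, 300 with 300 bp bins -> counts 2, 1, 0
  rs <- makeReadSet(c(1L, 300L, 301L), chromLen = 900)
  bt <- binReads(rs, 300)
  expect_equal(binCounts(bt)$chr1, c(2L, 1L, 0L))
  expect_equal(totalReads(bt), totalReads(rs))

  # trailing partial bin is kept
  rs2 <- makeReadSet(c(1L, 950L), chromLen = 950)
  expect_length(binCounts(binReads(rs2, 300))$chr1, 4L)
  expect_equal(sum(binCounts(binReads(rs2, 300))$chr1), 2L)
})

test_that("binReads matches a direct histogram oracle on uniform reads", {
  set.seed(11)
  starts <- sort(sample.int(1e6, 10000, replace = TRUE))
  bt <- binReads(makeReadSet(starts, chromLen = 1e6), 300)
  oracle <- as.integer(table(factor((starts - 1) %/% 300,
                                    levels = 0:(ceiling(1e6 / 300) - 1))))
  expect_equal(binCounts(bt)$chr1, oracle)
})

test_that("percentileThreshold follows the nonzero-bin percentile contract", {
  # constant nonzero track -> the constant, at any level
  bt <- BinTrack(c(rep(0L, 10), rep(5L, 30)))
  expect_equal(percentileThreshold(bt, 0.9), 5L)
  expect_equal(percentileThreshold(bt, 0.996), 5L)

  # 90 bins of 1 and 10 bins of 10 at level 0.90 -> 10
  bt2 <- BinTrack(c(rep(1L, 90), rep(10L, 10)))
  expect_equal(percentileThreshold(bt2, 0.90), 10L)

  # brute-force oracle and monotonicity on random tracks
  for (s in 1:5) {
    set.seed(s)
    cnt <- rpois(400, 2)
    bt3 <- BinTrack(cnt)
    levels <- c(0.5, 0.9, 0.95, 0.99, 0.996)
    thr <- vapply(levels, function(l) percentileThreshold(bt3, l),
                  numeric(1))
    orc <- vapply(levels, function(l) oraclePercentile(cnt, l), numeric(1))
    expect_equal(thr, orc)
    expect_true(all(diff(thr) >= 0))
  }
  expect_error(percentileThreshold(BinTrack(rep(0L, 10))), "zero")
})

test_that("callLoci finds no loci without enrichment and one locus for a spike", {
  chip <- BinTrack(rep(5L, 50))
  expect_length(callLoci(chip, chip, 0.9), 0L)

  spiked <- rep(2L, 50); spiked[20] <- 100L
  loci <- callLoci(BinTrack(spiked), BinTrack(rep(2L, 50)), 0.95)
  expect_length(loci, 1L)
  expect_equal(GenomicRanges::start(loci), 19L * 300L + 1L)
  expect_equal(GenomicRanges::end(loci), 20L * 300L)
  expect_equal(S4Vectors::mcols(loci)$summit, 19L * 300L + 150L)

  expect_error(callLoci(BinTrack(rep(2L, 50)), BinTrack(rep(2L, 40))),
               "geometry")
})

test_that("callLoci matches the brute-force bin-scanning oracle", {
  for (s in 1:8) {
    set.seed(s)
    nb <- 30                                 # <= 10 kb genome (includes gaps)
    chip <- rpois(nb, 2) + sample(c(0, 20), nb, TRUE, prob = c(0.85, 0.15))
    inp <- rpois(nb, 2)
    minGap <- sample(1:2, 1)
    tc <- BinTrack(chip); ti <- BinTrack(inp)
    thr <- percentileThreshold(tc, 0.8)
    got <- callLoci(tc, ti, 0.8, minGap = minGap)
    exp <- oracleLoci(chip, inp, 300, 30 * 300, thr, minGap)
    if (is.null(exp)) {
      expect_length(got, 0L)
    } else {
      expect_equal(GenomicRanges::start(got), exp$start)
      expect_equal(GenomicRanges::end(got), exp$end)
      expect_equal(S4Vectors::mcols(got)$summit, as.integer(exp$summit))
      expect_equal(S4Vectors::mcols(got)$score, exp$score)
    }
    # loci are sorted and non-overlapping
    if (length(got) > 1)
      expect_true(all(GenomicRanges::start(got)[-1] >
                        GenomicRanges::end(got)[-length(got)]))
  }
})

test_that("estimateFdr reports 0 without simulated loci and ~1 on null data", {
  # strong isolated spikes: simulated uniform reads cannot reach them
  spiked <- rep(1L, 200); spiked[c(50, 120)] <- 60L
  fdr <- estimateFdr(BinTrack(spiked), BinTrack(rep(1L, 200)),
                     percentileLevels = 0.99, nSimulatedReads = sum(spiked),
                     seed = 1)
  expect_equal(fdr$simulated, 0L)
  expect_equal(fdr$fdr, 0)

  # chip itself uniform-random -> FDR near 1 at every level (20 seeds)
  fdrs <- sapply(1:20, function(s) {
    set.seed(s)
    chip <- BinTrack(rpois(1000, 3))
    inp <- BinTrack(rpois(1000, 3) * 0L + 3L)  # flat input
    estimateFdr(chip, inp, percentileLevels = c(0.99, 0.95),
                nSimulatedReads = totalReads(chip), seed = s + 500)$fdr
  })
  expect_true(all(rowMeans(fdrs) > 0.7))
})

test_that("estimateFdr is non-increasing as the level tightens on planted peaks", {
  lens <- c(chr1 = 900000)
  g <- syntheticGenome(lens, nGenes = 40, seed = 3)
  plan <- plantPeakPlan(g, nStimOnly = 20L, nUnstimOnly = 0L, nBasal = 0L,
                        nShift = 0L, minSpacing = 5000, seed = 4)
  chip <- binReads(generateReads(g, plan, "stimulated", 0.01, seed = 5))
  inp <- binReads(generateReads(g, plan, "input", 0.01, seed = 6))
  fdr <- estimateFdr(chip, inp, c(0.999, 0.996, 0.99, 0.95), seed = 7)
  # rows are ordered tightest level first
  expect_equal(fdr$level, sort(fdr$level, decreasing = TRUE))
  expect_true(all(diff(fdr$fdr) >= -1e-12))
  expect_true(all(diff(fdr$threshold) <= 0))
  expect_true(all(fdr$fdr >= 0 & fdr$fdr <= 1))
})
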