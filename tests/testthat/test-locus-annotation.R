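mkLoci <- function(summits, chrom = "chr1", chromLen = 2e6) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(summits - 150, summits + 149),
    seqlengths = stats::setNames(chromLen, unique(chrom)))
  S4Vectors::mcols(gr)$summit <- as.integer(summits)
  gr
}

test_that("assignToGenes anchors signed distances at the TSS", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(50000, 400000),
                      tes = c(60000, 390000))
  a <- assignToGenes(mkLoci(c(50000, 45000, 405000, 200000)), genes)
  expect_equal(a$gene_id, c("gA", "gA", "gB", NA))
  expect_equal(a$distance[1], 0)          # summit exactly at the + TSS
  expect_true(a$promoter[1])
  expect_equal(a$distance[2], -5000)      # 5 kb upstream on + strand
  # on the - strand, larger coordinate means upstream
  expect_equal(a$distance[3], -5000)
  expect_true(is.na(a$distance[4]))       # 150 kb away -> unassigned

  expect_error(assignToGenes(mkLoci(1000, chrom = "chrX"), genes),
               "unknown")
})

test_that("assignToGenes matches the all-pairs nearest-TSS oracle", {
  set.seed(21)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      chrom = sample(c("chr1", "chr2"), 10, TRUE),
                      strand = sample(c("+", "-"), 10, TRUE),
                      tss = sample.int(2e6, 10), tes = NA)
  genes$tes <- ifelse(genes$strand == "+", genes$tss + 5000,
                      genes$tss - 5000)
  summits <- sample.int(2e6, 50)
  chroms <- sample(c("chr1", "chr2"), 50, TRUE)
  gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(summits, width = 1),
    seqlengths = c(chr1 = 2e6, chr2 = 2e6))
  S4Vectors::mcols(gr)$summit <- summits
  a <- assignToGenes(gr, genes, window = 100000)
  o <- oracleAssign(summits, chroms, genes, window = 100000)
  expect_equal(a$gene_id, o$gene_id)
  expect_equal(a$distance, o$distance)
})

test_that("tssDistanceHistogram bins distances and conserves assigned loci", {
  a <- data.frame(gene_id = c("g", "g", "g", NA),
                  distance = c(0, 0, -15000, NA),
                  promoter = c(TRUE, TRUE, FALSE, FALSE))
  h <- tssDistanceHistogram(a, 10000)
  expect_equal(sum(h$count), 3L)                 # unassigned excluded
  expect_equal(h$count[h$bin_start == 0], 2L)    # both TSS loci in bin [0, 1e4)
  expect_equal(h$count[h$bin_start == -20000], 1L)

  set.seed(5)
  d <- runif(100, -1e5, 1e5)
  a2 <- data.frame(gene_id = "g", distance = d, promoter = FALSE)
  h2 <- tssDistanceHistogram(a2, 10000)
  oracle <- table(floor(d / 10000))
  expect_equal(h2$count, as.integer(oracle))
})

test_that("classifyPatterns applies the 1 kb Basal/Shift rule to single pairs", {
  stim <- data.frame(gene_id = "g1", summit = 5000)
  unstim <- data.frame(gene_id = "g1", summit = 5400)
  calls <- classifyPatterns(stim, unstim)
  expect_equal(calls$category, "Basal")
  expect_equal(calls$distance, 400)

  unstim2 <- data.frame(gene_id = "g1", summit = 7500)
  expect_equal(classifyPatterns(stim, unstim2)$category, "Shift")
})

test_that("classifyPatterns matches the greedy pairing oracle and partitions loci", {
  for (s in 1:6) {
    set.seed(s)
    nS <- 16; nU <- 14
    stim <- data.frame(gene_id = sample(sprintf("g%02d", 1:10), nS, TRUE),
                       summit = sample.int(5e4, nS))
    unstim <- data.frame(gene_id = sample(sprintf("g%02d", 1:10), nU, TRUE),
                         summit = sample.int(5e4, nU))
    calls <- classifyPatterns(stim, unstim, shiftThreshold = 1000)
    # per-gene category multiset equals the oracle's
    for (g in unique(c(stim$gene_id, unstim$gene_id))) {
      got <- sort(calls$category[calls$gene_id == g])
      exp <- sort(oraclePairCategories(stim$summit[stim$gene_id == g],
                                       unstim$summit[unstim$gene_id == g],
                                       1000))
      expect_equal(got, exp)
    }
    # every gene-assigned locus appears in exactly one call
    expect_equal(sum(!is.na(calls$stim_summit)), nS)
    expect_equal(sum(!is.na(calls$unstim_summit)), nU)
    # Basal and Shift pair counts are symmetric between conditions
    ps <- patternSummary(calls, "stimulated")
    pu <- patternSummary(calls, "unstimulated")
    expect_equal(ps$count[ps$category == "Basal"],
                 pu$count[pu$category == "Basal"])
    expect_equal(ps$count[ps$category == "Shift"],
                 pu$count[pu$category == "Shift"])
    expect_equal(attr(ps, "total"), nS)
    expect_equal(sum(ps$count), nS)
  }
})

test_that("patternSummary percentages are half-up at one decimal", {
  calls <- data.frame(gene_id = "g", category = "StimulatedOnly",
                      stim_summit = 1, unstim_summit = NA, distance = NA)
  ps <- patternSummary(calls, "stimulated")
  expect_equal(ps$percent[ps$category == "StimulatedOnly"], 100.0)
  expect_equal(sum(ps$count), 1L)
})
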