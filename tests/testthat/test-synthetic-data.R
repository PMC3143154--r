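test_that("syntheticGenome satisfies its structural invariants", {
  g <- syntheticGenome(c(chr1 = 5e5, chr2 = 3e5), nGenes = 40, seed = 2)
  gm <- geneModels(g)
  expect_equal(nrow(gm), 40L)
  expect_false(anyDuplicated(gm$gene_id) > 0)
  plus <- gm$strand == "+"
  expect_true(all(gm$tss[plus] < gm$tes[plus]))
  expect_true(all(gm$tss[!plus] > gm$tes[!plus]))
  lim <- chromLengths(g)[gm$chrom]
  expect_true(all(pmax(gm$tss, gm$tes) <= lim))
})

test_that("generateReads conserves counts, is seed-stable and checks bounds", {
  g <- syntheticGenome(c(chr1 = 2e5), nGenes = 5, seed = 1)
  # no peaks: exact count, roughly uniform occupancy
  rs <- generateReads(g, condition = "input", backgroundDensity = 0.005,
                      nReads = 1000, seed = 3)
  expect_equal(totalReads(rs), 1000L)
  halves <- table(GenomicRanges::start(reads(rs)) > 1e5)
  expect_true(all(abs(halves - 500) < 4 * sqrt(1000 * 0.25)))

  rs2 <- generateReads(g, condition = "input", backgroundDensity = 0.005,
                       nReads = 1000, seed = 3)
  expect_identical(GenomicRanges::start(reads(rs)),
                   GenomicRanges::start(reads(rs2)))

  bad <- plantedPeaks("chr1", center = 2e5, width = 300)
  expect_error(generateReads(g, bad, "stimulated", 0.005, 100, seed = 1),
               "bounds")
  expect_error(plantedPeaks("chr1", 1000, enrichment = 1), "exceed")
})

test_that("a planted peak enriches its window against the flanks", {
  g <- syntheticGenome(c(chr1 = 3e5), nGenes = 5, seed = 1)
  peak <- plantedPeaks("chr1", center = 150150, enrichment = 20,
                       width = 300)
  inWin <- sapply(1:20, function(s) {
    rs <- generateReads(g, peak, "stimulated", backgroundDensity = 0.01,
                        seed = s)
    st <- GenomicRanges::start(reads(rs))
    c(sum(st >= 150001 & st <= 150300),
      sum(st >= 149701 & st <= 150000),
      sum(st >= 150301 & st <= 150600))
  })
  # 20x enrichment: the window beats both flanks in every one of 20 seeds
  # (binomial tail at these densities leaves ~1e-8 failure mass per seed)
  expect_true(all(inWin[1, ] > inWin[2, ]))
  expect_true(all(inWin[1, ] > inWin[3, ]))
})

test_that("generateExpression plants exact means at zero noise", {
  g <- syntheticGenome(c(chr1 = 1e5), nGenes = 10, seed = 4)
  de <- geneModels(g)$gene_id[1:2]
  ex <- generateExpression(g, de, log2Effect = 3, noiseSd = 0,
                           nReplicates = 3, seed = 5)
  m <- ex$matrix
  un <- ex$groups == "unstimulated"
  expect_true(all(m[, un] == m[, un][, 1]))    # replicates identical
  diff <- rowMeans(m[, !un]) - rowMeans(m[, un])
  expect_equal(unname(diff[de]), c(3, -3))     # alternating signs
  expect_true(all(diff[setdiff(rownames(m), de)] == 0))

  expect_error(generateExpression(g, "ghost"), "unknown gene")
  expect_error(generateExpression(g, character(0), nReplicates = 1),
               "replicates")
})

test_that("generateLocusSequences respects lengths, planting and edge cases", {
  pwm <- pwmFromConsensus("ACGTACGT", strength = 1, pseudocount = 0)
  lens <- c(120L, 80L, 200L, 50L)
  seqs <- generateLocusSequences(lens, pwm, plantedFraction = 1, seed = 6)
  expect_equal(unname(Biostrings::width(seqs)), as.integer(lens))
  # degenerate-free PWM at fraction 1: consensus or its reverse complement
  # appears in every sequence
  hasCons <- vapply(as.character(seqs), function(s)
    grepl("ACGTACGT", s) ||
      grepl("ACGTACGT", as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))), logical(1))
  expect_true(all(hasCons))
  expect_true(all(S4Vectors::mcols(seqs)$planted))

  s0 <- generateLocusSequences(lens, plantedFraction = 0, seed = 7)
  expect_false(any(S4Vectors::mcols(s0)$planted))
  expect_error(generateLocusSequences(c(5L, 200L), pwm, 1, seed = 1),
               "longer")
})

test_that("generateCohort plants groups, censoring and hazards as specified", {
  sp <- plantedCohortSpec(nPatients = 80, nGenes = 50,
                          prognosticGenes = 1:12, effectSize = 2,
                          hazardRatio = 3, censoringFraction = 0,
                          seed = 9)
  co <- generateCohort(sp)
  sv <- survivalData(co)
  expect_equal(dim(expressionMatrix(co)), c(50L, 80L))
  expect_equal(sum(sv$event), 80)                   # no censoring
  expect_equal(as.vector(table(sv$planted_group)), c(40, 40))
  # planted separation on the prognostic genes
  d <- rowMeans(expressionMatrix(co)[prognosticGenes(co),
                                     sv$planted_group == 2]) -
    rowMeans(expressionMatrix(co)[prognosticGenes(co),
                                  sv$planted_group == 1])
  expect_equal(mean(d), 2, tolerance = 0.4)

  sp2 <- plantedCohortSpec(nPatients = 80, nGenes = 50,
                           prognosticGenes = 1:12,
                           censoringFraction = 0.25, seed = 9)
  co2 <- generateCohort(sp2)
  expect_equal(sum(survivalData(co2)$event == 0), 20L)

  expect_identical(expressionMatrix(generateCohort(sp)),
                   expressionMatrix(co))            # seed determinism
  expect_error(plantedCohortSpec(nGenes = 10, prognosticGenes = 1:20),
               "within")
  expect_error(plantedCohortSpec(hazardRatio = 0), "positive")
})
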