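library(TFscape)

syntheticLibrary <- function() {
  readPWMLibrary(system.file("extdata", "pwm_library_synthetic.txt",
                             package = "TFscape"))
}

test_that("findHubTFs flags nothing when targets equal background", {
  pw <- syntheticLibrary()
  seqs <- generateLocusSequences(rep(300L, 30), plantedFraction = 0,
                                 seed = 2)
  sc <- findHubTFs(seqs, seqs, pw)
  expect_false(any(sc$hub))
  expect_error(findHubTFs(seqs, seqs, list()), "empty")
})

test_that("a planted motif is ranked first and its Fisher p matches the table", {
  pw <- syntheticLibrary()
  tg <- generateLocusSequences(rep(300L, 50), pw$SBE_SYNTH, 0.8, seed = 3)
  bg <- generateLocusSequences(rep(300L, 50), plantedFraction = 0, seed = 4)
  sc <- findHubTFs(tg, bg, pw)
  expect_equal(sc$motif[1], "SBE_SYNTH")
  expect_true(sc$hub[1])
  # cross-check the reported p against fisher.test on the reported table
  r <- sc[1, ]
  ft <- fisher.test(matrix(c(r$target_hits, r$target_n - r$target_hits,
                             r$background_hits,
                             r$background_n - r$background_hits), 2),
                    alternative = "greater")
  expect_equal(r$p, ft$p.value)
})

test_that("buildNetwork wires edges exactly where the scan finds hits", {
  pw <- syntheticLibrary()
  hubs <- c("SBE_SYNTH", "MOTIF_01")
  set.seed(6)
  geneLoci <- lapply(1:8, function(i)
    as.character(generateLocusSequences(rep(300L, sample(1:2, 1)),
                                        plantedFraction = 0, seed = i)))
  names(geneLoci) <- sprintf("g%02d", 1:8)
  # plant one clean consensus into gene g03
  geneLoci$g03[1] <- paste0(substr(geneLoci$g03[1], 1, 100), "GTCTAGAC",
                            substr(geneLoci$g03[1], 109, 300))
  expr <- data.frame(gene_id = names(geneLoci),
                     log2fc = rep(c(1, -1), 4))
  net <- buildNetwork(hubs, pw, geneLoci, expr, scoreFraction = 0.8)
  e <- networkEdges(net)
  # scan-then-join oracle over every hub x gene pair
  for (tf in hubs) for (g in names(geneLoci)) {
    hits <- sum(vapply(geneLoci[[g]], function(s)
      nrow(scanPWM(s, pw[[tf]], 0.8)), integer(1)))
    inNet <- any(e$tf == tf & e$gene == g)
    expect_equal(inNet, hits > 0)
    if (inNet) expect_equal(e$hits[e$tf == tf & e$gene == g], hits)
  }
  expect_true(any(e$tf == "SBE_SYNTH" & e$gene == "g03"))
  nd <- networkNodes(net)
  expect_equal(nd$direction[nd$id == "g03"], "up")
  expect_equal(sum(nd$type == "hub"), 2L)

  # genes without sequences are skipped with a warning
  geneLoci2 <- c(geneLoci, list(g99 = character(0)))
  expect_warning(buildNetwork(hubs, pw, geneLoci2, expr), "g99")
})

test_that("network SIF export round-trips", {
  pw <- syntheticLibrary()
  geneLoci <- list(gA = paste0(strrep("AC", 60), "GTCTAGAC",
                               strrep("TG", 60)))
  expr <- data.frame(gene_id = "gA", log2fc = -2)
  net <- buildNetwork("SBE_SYNTH", pw, geneLoci, expr)
  sif <- tempfile(fileext = ".sif")
  writeNetworkSIF(net, sif, paste0(sif, ".attrs.tsv"))
  back <- readNetworkSIF(sif)
  expect_equal(back$tf, networkEdges(net)$tf)
  expect_equal(back$gene, networkEdges(net)$gene)
  expect_equal(unique(back$relation), "regulates")
})

test_that("permutationEdgeTest respects the add-one estimator and finds planted signal", {
  pw <- syntheticLibrary()
  # no observed hits -> every permutation ties -> p = 1
  flat <- strrep("AT", 150)
  r0 <- permutationEdgeTest(flat, pw$SBE_SYNTH, nPermutations = 100,
                            seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p, 1)
  expect_error(permutationEdgeTest(flat, pw$SBE_SYNTH, nPermutations = 50),
               "100")

  # strong planted consensus in a random 300-mer -> small p across seeds
  set.seed(8)
  for (s in 1:4) {
    nt <- sample(c("A", "C", "G", "T"), 300, TRUE)
    nt[140:147] <- strsplit("GTCTAGAC", "")[[1]]
    r <- permutationEdgeTest(paste(nt, collapse = ""), pw$SBE_SYNTH,
                             nPermutations = 199, seed = s)
    expect_gte(r$observed, 1L)
    expect_lte(r$p, 0.01)
    expect_gte(r$p, 1 / 200)
  }
})
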