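#' @include AllGenerics.R
NULL

#' Pipeline configuration with published defaults
#'
#' Collects every tunable parameter of the end-to-end pipeline. Analysis
#' defaults are the study constants (300 bp bins at acceptance level 0.996
#' against input; +/-100 kb gene window; +/-8 kb promoter; 1 kb Basal/Shift
#' cutoff; |log2 FC| > 0.5 at p < 0.1, strict p 0.05; four gene and four
#' patient groups); generator settings define the bundled synthetic fixture
#' (see the vignette for the sizing rationale).
#'
#' @param ... overrides of the defaults listed in the source.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # analysis constants
    binWidth = 300L, percentileLevel = 0.996,
    fdrLevels = c(0.999, 0.996, 0.99, 0.95), minGap = 1L,
    geneWindow = 1e5, promoterWindow = 8000, shiftThreshold = 1000,
    fcThreshold = 0.5, pThreshold = 0.1, pStrict = 0.05,
    scoreFraction = 0.8, alpha = 0.05, nPermutations = 199L,
    kGene = 4L, kPatient = 4L,
    # synthetic fixture: genome, planted peaks, expression
    chromLength = 1800000, nChrom = 2L, nGenes = 100L,
    backgroundDensity = 0.004, enrichment = 15, peakWidth = 300,
    nStimOnly = 14L, nUnstimOnly = 14L, nBasal = 8L, nShift = 8L,
    basalOffset = 300, shiftOffset = 3000,
    nDePeakGenes = 22L, nDeOtherGenes = 8L, log2Effect = 2,
    noiseSd = 0.3, nReplicates = 3L,
    # synthetic fixture: motifs and cohort
    plantedMotif = "SBE_SYNTH", plantedMotifFraction = 0.8,
    cohortPatients = 153L, cohortGenes = 187L, cohortPrognostic = 49L,
    cohortEffect = 3, cohortHazardRatio = 4,
    cohortBaselineHazard = log(2) / 63, cohortCensoring = 0.15,
    cohortMissing = 29 / 153,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validateConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

.validateConfig <- function(cfg) {
  .checkProportion(cfg$percentileLevel, "percentileLevel", TRUE, TRUE)
  .checkProportion(cfg$pThreshold, "pThreshold", TRUE, TRUE)
  .checkProportion(cfg$pStrict, "pStrict", TRUE, TRUE)
  .checkProportion(cfg$scoreFraction, "scoreFraction", open_lower = TRUE)
  if (cfg$binWidth < 1L) stop("binWidth must be positive")
  if (cfg$fcThreshold < 0) stop("fcThreshold must be non-negative")
  if (cfg$shiftThreshold <= 0) stop("shiftThreshold must be positive")
  invisible(cfg)
}

#' Write / read a pipeline configuration as flat key = value text
#'
#' @param cfg a [pipelineConfig()] object.
#' @param path file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  fmt <- vapply(cfg, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ","), character(1))
  writeLines(paste(names(cfg), fmt, sep = " = "), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @return `readPipelineConfig()`: the configuration, with values coerced to
#'   the types of the defaults.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  keys <- trimws(keys)
  vals <- vapply(kv, `[`, character(1), 2L)
  ref <- pipelineConfig()
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(ref)) stop("unknown configuration key: ", k)
    v <- strsplit(vals[i], ",")[[1L]]
    proto <- ref[[k]]
    out[[k]] <- if (is.integer(proto)) as.integer(v)
                else if (is.numeric(proto)) as.numeric(v)
                else as.character(v)
  }
  do.call(pipelineConfig, out)
}

#' Plan planted peaks around gene TSSs
#'
#' Selects distinct genes and plants one peak per gene near its TSS, with
#' the requested mix of condition-specific and paired (Basal / Shift)
#' peaks. Peak centers are snapped to bin centers so each planted peak
#' occupies exactly one bin, making planted-truth accounting exact, and are
#' kept at least `minSpacing` bp apart.
#'
#' @param genome a [SyntheticGenome-class].
#' @param nStimOnly,nUnstimOnly,nBasal,nShift category counts.
#' @param enrichment,width peak shape (defaults 15x, 300 bp).
#' @param binWidth bin width used for center snapping (default 300).
#' @param basalOffset,shiftOffset unstimulated-copy offsets for the paired
#'   categories (defaults 300 and 3000 bp).
#' @param minSpacing minimal distance between planted centers (default
#'   10000).
#' @param seed integer seed.
#' @return [plantedPeaks()] data.frame with ground-truth `geneId` and
#'   `condition`.
#' @export
plantPeakPlan <- function(genome, nStimOnly = 14L, nUnstimOnly = 14L,
                          nBasal = 8L, nShift = 8L, enrichment = 15,
                          width = 300, binWidth = 300L, basalOffset = 300,
                          shiftOffset = 3000, minSpacing = 10000,
                          seed = 1L) {
  g <- geneModels(genome)
  lens <- chromLengths(genome)
  need <- nStimOnly + nUnstimOnly + nBasal + nShift
  cond <- c(rep("stimulated", nStimOnly), rep("unstimulated", nUnstimOnly),
            rep("both", nBasal + nShift))
  off <- c(rep(0, nStimOnly + nUnstimOnly), rep(basalOffset, nBasal),
           rep(shiftOffset, nShift))
  withr::with_seed(seed, {
    ord <- sample.int(nrow(g))
    chosen <- list()
    centers <- list()
    slot <- 1L
    for (i in ord) {
      if (slot > need) break
      tss <- g$tss[i]; chr <- g$chrom[i]
      bc <- floor(tss / binWidth) * binWidth + ceiling(binWidth / 2)
      lo <- bc - floor(width / 2) + 1
      hi <- bc + max(basalOffset, shiftOffset) + width
      if (lo < 1 || hi > lens[[chr]]) next
      prev <- centers[[chr]]
      if (!is.null(prev) &&
          any(abs(prev - bc) < minSpacing + max(basalOffset, shiftOffset)))
        next
      # the linked gene must stay the strictly nearest TSS for both peaks
      # of a planted pair, or the classification ground truth is ambiguous
      samechr <- g$chrom == chr & g$gene_id != g$gene_id[i]
      otherT <- g$tss[samechr]
      pc <- bc + off[slot]
      if (length(otherT) &&
          (min(abs(otherT - bc)) <= abs(tss - bc) + off[slot] ||
           min(abs(otherT - pc)) <= abs(tss - pc)))
        next
      centers[[chr]] <- c(prev, bc)
      chosen[[length(chosen) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], chrom = chr, center = bc,
        condition = cond[slot], pairOffset = off[slot],
        stringsAsFactors = FALSE)
      slot <- slot + 1L
    }
    if (length(chosen) < need)
      stop("could not place ", need, " non-overlapping peaks; ",
           "use a larger genome or fewer peaks")
    ch <- do.call(rbind, chosen)
    plantedPeaks(chrom = ch$chrom, center = ch$center,
                 enrichment = enrichment, width = width,
                 condition = ch$condition, pairOffset = ch$pairOffset,
                 geneId = ch$gene_id)
  })
}

#' Realized planted peak centers for one condition
#'
#' @param peaks [plantedPeaks()] data.frame.
#' @param condition `"stimulated"` or `"unstimulated"`.
#' @return data.frame with chrom, center, geneId, category (the planted
#'   pattern category from that condition's perspective).
#' @export
plantedCenters <- function(peaks, condition) {
  win <- .peakWindows(peaks, condition)
  cat <- ifelse(win$condition != "both",
                ifelse(condition == "stimulated", "StimulatedOnly",
                       "UnstimulatedOnly"),
                ifelse(win$pairOffset <= 1000, "Basal", "Shift"))
  data.frame(chrom = win$chrom, center = win$center, geneId = win$geneId,
             category = cat, stringsAsFactors = FALSE)
}

#' Recovery of planted peaks by called loci
#'
#' A planted peak is recovered when a called locus summit lies within
#' `tolerance` bp of its realized center; a called locus is a false call
#' when its summit is not within `tolerance` of any planted center.
#'
#' @param loci `GRanges` from [callLoci()].
#' @param planted data.frame from [plantedCenters()].
#' @param tolerance matching distance in bp (default 300).
#' @return list: recall, n_recovered, n_planted, n_false, n_called,
#'   empirical_fdr.
#' @export
peakRecovery <- function(loci, planted, tolerance = 300) {
  if (!length(loci))
    return(list(recall = 0, n_recovered = 0L, n_planted = nrow(planted),
                n_false = 0L, n_called = 0L, empirical_fdr = 0))
  chrom <- as.character(GenomicRanges::seqnames(loci))
  summit <- S4Vectors::mcols(loci)$summit
  near <- function(chr, pos)
    any(planted$chrom == chr & abs(planted$center - pos) <= tolerance)
  falseCall <- !mapply(near, chrom, summit)
  recovered <- vapply(seq_len(nrow(planted)), function(i)
    any(chrom == planted$chrom[i] &
          abs(summit - planted$center[i]) <= tolerance), logical(1))
  list(recall = mean(recovered), n_recovered = sum(recovered),
       n_planted = nrow(planted), n_false = sum(falseCall),
       n_called = length(loci),
       empirical_fdr = sum(falseCall) / length(loci))
}

#' Run the full pipeline on the bundled synthetic fixture
#'
#' Generates the synthetic inputs defined by the configuration (reads for
#' both ChIP conditions plus input, expression matrix, locus sequences with
#' a planted motif, patient cohort), then runs peak calling with FDR
#' estimation, locus annotation and binding-pattern classification,
#' differential-expression integration, hub-TF network inference with
#' permutation-tested edges, and the signature survival scan. Every stage
#' seed derives deterministically from the global seed, so the report is
#' reproducible bit for bit.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional directory for TSV/BED/SIF/FASTA outputs; `NULL`
#'   (default) computes the report only.
#' @return nested report list (also written as JSON when `outDir` is set).
#' @export
runAll <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  lens <- stats::setNames(rep(config$chromLength, config$nChrom),
                          paste0("chr", seq_len(config$nChrom)))

  ## --- simulate ---------------------------------------------------------
  genome <- syntheticGenome(lens, nGenes = config$nGenes,
                            seed = stageSeed(seed, "genome"))
  peaks <- plantPeakPlan(genome, nStimOnly = config$nStimOnly,
                         nUnstimOnly = config$nUnstimOnly,
                         nBasal = config$nBasal, nShift = config$nShift,
                         enrichment = config$enrichment,
                         width = config$peakWidth,
                         binWidth = config$binWidth,
                         basalOffset = config$basalOffset,
                         shiftOffset = config$shiftOffset,
                         seed = stageSeed(seed, "plan"))
  rs <- list(
    stimulated = generateReads(genome, peaks, "stimulated",
                               config$backgroundDensity,
                               seed = stageSeed(seed, "reads-stim")),
    unstimulated = generateReads(genome, peaks, "unstimulated",
                                 config$backgroundDensity,
                                 seed = stageSeed(seed, "reads-unstim")),
    input = generateReads(genome, peaks, "input",
                          config$backgroundDensity,
                          seed = stageSeed(seed, "reads-input")))

  ## --- peak calling -----------------------------------------------------
  tracks <- lapply(rs, binReads, binWidth = config$binWidth)
  loci <- list(
    stimulated = callLoci(tracks$stimulated, tracks$input,
                          config$percentileLevel, config$minGap,
                          condition = "stimulated"),
    unstimulated = callLoci(tracks$unstimulated, tracks$input,
                            config$percentileLevel, config$minGap,
                            condition = "unstimulated"))
  fdr <- estimateFdr(tracks$stimulated, tracks$input, config$fdrLevels,
                     seed = stageSeed(seed, "fdr"))
  recovery <- lapply(c(stimulated = "stimulated",
                       unstimulated = "unstimulated"), function(cond)
    peakRecovery(loci[[cond]], plantedCenters(peaks, cond)))

  ## --- annotation and patterns -----------------------------------------
  genes <- geneModels(genome)
  assign <- lapply(loci, assignToGenes, genes = genes,
                   window = config$geneWindow,
                   promoterWindow = config$promoterWindow)
  calls <- classifyPatterns(assign$stimulated, assign$unstimulated,
                            config$shiftThreshold)
  patt <- list(stimulated = patternSummary(calls, "stimulated"),
               unstimulated = patternSummary(calls, "unstimulated"))
  planted_cat <- plantedCenters(peaks, "stimulated")
  planted_cat <- rbind(planted_cat, plantedCenters(peaks, "unstimulated"))
  planted_cat <- unique(planted_cat[, c("geneId", "category")])
  # per planted gene-category: does some call of that gene carry it?
  cat_hit <- vapply(seq_len(nrow(planted_cat)), function(i)
    any(calls$gene_id == planted_cat$geneId[i] &
          calls$category == planted_cat$category[i]), logical(1))

  ## --- expression integration ------------------------------------------
  stimGenes <- unique(plantedCenters(peaks, "stimulated")$geneId)
  deTargets <- utils::head(stimGenes, config$nDePeakGenes)
  others <- setdiff(genes$gene_id, unique(peaks$geneId))
  deOthers <- utils::head(others, config$nDeOtherGenes)
  expr <- generateExpression(genome, c(deTargets, deOthers),
                             log2Effect = config$log2Effect,
                             noiseSd = config$noiseSd,
                             nReplicates = config$nReplicates,
                             seed = stageSeed(seed, "expression"))
  de <- differentialExpression(expr$matrix, expr$groups,
                               treatment = "stimulated",
                               fcThreshold = config$fcThreshold,
                               pThreshold = config$pThreshold)
  targetIds <- unique(assign$stimulated$gene_id[
    !is.na(assign$stimulated$gene_id)])
  part <- integrateTargets(de, targetIds)
  strict <- strictVariant(de, targetIds, pThreshold = config$pStrict,
                          fcThreshold = config$fcThreshold)
  deRecall <- mean(c(deTargets, deOthers) %in% de$gene_id[de$de])

  ## --- network inference ------------------------------------------------
  pwmPath <- system.file("extdata", "pwm_library_synthetic.txt",
                         package = "TFscape", mustWork = TRUE)
  pwms <- readPWMLibrary(pwmPath)
  netGenes <- part$deAndLocus
  tloci <- loci$stimulated[!is.na(assign$stimulated$gene_id) &
                             assign$stimulated$gene_id %in% netGenes]
  tgene <- assign$stimulated$gene_id[!is.na(assign$stimulated$gene_id) &
                                       assign$stimulated$gene_id %in%
                                       netGenes]
  names(tloci) <- sprintf("%s_locus%02d", tgene, seq_along(tloci))
  targetSeqs <- generateLocusSequences(
    tloci, pwms[[config$plantedMotif]],
    plantedFraction = config$plantedMotifFraction,
    seed = stageSeed(seed, "target-seqs"))
  bgSeqs <- generateLocusSequences(GenomicRanges::width(tloci),
                                   plantedFraction = 0,
                                   seed = stageSeed(seed, "bg-seqs"))
  screen <- findHubTFs(targetSeqs, bgSeqs, pwms, config$scoreFraction,
                       config$alpha)
  geneLoci <- split(as.character(targetSeqs), tgene)
  network <- buildNetwork(screen, pwms, geneLoci, de, config$scoreFraction)
  network <- testNetworkEdges(network, pwms, geneLoci,
                              nPermutations = config$nPermutations,
                              seed = stageSeed(seed, "permutation"))

  ## --- signature survival ----------------------------------------------
  cspec <- plantedCohortSpec(
    nPatients = config$cohortPatients, nGenes = config$cohortGenes,
    prognosticGenes = seq_len(config$cohortPrognostic),
    effectSize = config$cohortEffect,
    baselineHazard = config$cohortBaselineHazard,
    hazardRatio = config$cohortHazardRatio,
    censoringFraction = config$cohortCensoring,
    missingSurvivalFraction = config$cohortMissing,
    seed = stageSeed(seed, "cohort"))
  cohort <- generateCohort(cspec)
  scan <- signatureScan(cohort, kGene = config$kGene,
                        kPatient = config$kPatient)
  planted <- prognosticGenes(cohort)
  sigOverlap <- length(intersect(scan$selected_genes, planted)) /
    length(planted)
  # size-matched draw, capped by the available non-signature genes when the
  # selected cluster covers more than half the candidate set
  ctrlSize <- min(length(scan$selected_genes),
                  nrow(cohort) - length(scan$selected_genes))
  control <- randomSignatureControl(cohort, ctrlSize, scan$selected_genes,
                                    kPatient = config$kPatient,
                                    seed = stageSeed(seed, "control"))

  ep <- networkEdges(network)$p
  report <- list(
    parameters = unclass(config),
    peaks = list(
      n_stimulated = length(loci$stimulated),
      n_unstimulated = length(loci$unstimulated),
      stimulated_recovery = recovery$stimulated,
      unstimulated_recovery = recovery$unstimulated,
      fdr_table = fdr),
    annotation = list(
      stimulated = assignmentSummary(assign$stimulated),
      unstimulated = assignmentSummary(assign$unstimulated)),
    patterns = list(
      stimulated = patt$stimulated,
      stimulated_total = attr(patt$stimulated, "total"),
      unstimulated = patt$unstimulated,
      unstimulated_total = attr(patt$unstimulated, "total"),
      planted_category_recovery = mean(cat_hit),
      percent_sum_stimulated = sum(patt$stimulated$percent),
      percent_sum_unstimulated = sum(patt$unstimulated$percent)),
    expression = list(
      n_de = part$summary$n_de, partition = part$summary,
      strict = strict$summary, planted_de_recall = deRecall),
    network = list(
      hub_motifs = screen$motif[screen$hub],
      planted_motif_rank = match(config$plantedMotif, screen$motif),
      n_edges = nrow(networkEdges(network)),
      min_edge_p = if (length(ep)) min(ep) else NA,
      median_edge_p = if (length(ep)) stats::median(ep) else NA),
    survival = list(
      selected_group = scan$selected,
      n_selected_genes = length(scan$selected_genes),
      planted_overlap = sigOverlap,
      best_logrank_p = scan$best_p,
      control_logrank_p = control$best_p,
      medians = scan$perGroup[[scan$selected]]$km$medians))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGeneTable(genes, file.path(outDir, "genes.tsv"))
    for (cond in names(rs))
      writeMappedReads(rs[[cond]], file.path(outDir,
                                             paste0("reads_", cond, ".bed")))
    for (cond in names(loci))
      writeLociBed(loci[[cond]], file.path(outDir,
                                           paste0("loci_", cond, ".bed")))
    utils::write.table(fdr, file.path(outDir, "fdr_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(outDir, "pattern_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeMatrixTSV(expr$matrix, file.path(outDir, "expression.tsv"))
    utils::write.table(de, file.path(outDir, "de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeFastaSeqs(targetSeqs, file.path(outDir, "target_loci.fa"))
    writeNetworkSIF(network, file.path(outDir, "network.sif"),
                    file.path(outDir, "network_attributes.tsv"))
    writeMatrixTSV(expressionMatrix(cohort),
                   file.path(outDir, "cohort_expression.tsv"))
    writeSurvivalTSV(survivalData(cohort),
                     file.path(outDir, "cohort_survival.tsv"))
    writeRunReport(report, file.path(outDir, "report.json"))
  }
  report
}

#' Serialise a run report as JSON
#'
#' @param report list from [runAll()].
#' @param path output path.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
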