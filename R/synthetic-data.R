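#' @include AllGenerics.R
NULL

#' Generate a synthetic genome with gene models
#'
#' Draws `nGenes` non-identical gene models uniformly over the chromosomes
#' (TSS kept away from the chromosome ends by a small margin, gene lengths
#' uniform between `geneLengthRange`), with random strands. Strand-aware:
#' `tss < tes` on `+`, `tss > tes` on `-`.
#'
#' @param chromLengths named numeric chromosome lengths in bp.
#' @param nGenes number of gene models.
#' @param seed integer seed.
#' @param geneLengthRange min/max gene length in bp.
#' @return a [SyntheticGenome-class].
#' @export
syntheticGenome <- function(chromLengths, nGenes = 60L, seed = 1L,
                            geneLengthRange = c(2000, 20000)) {
  stopifnot(length(chromLengths) >= 1L, !is.null(names(chromLengths)))
  genes <- withr::with_seed(seed, {
    chrom <- sample(names(chromLengths), nGenes, replace = TRUE,
                    prob = chromLengths / sum(chromLengths))
    margin <- pmin(0.02 * chromLengths[chrom],
                   max(geneLengthRange) + 1000)
    tss <- floor(stats::runif(nGenes, margin,
                              chromLengths[chrom] - margin))
    len <- floor(stats::runif(nGenes, geneLengthRange[1L],
                              geneLengthRange[2L]))
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    tes <- ifelse(strand == "+",
                  pmin(tss + len, chromLengths[chrom] - 1),
                  pmax(tss - len, 2))
    data.frame(gene_id = sprintf("gene_%04d", seq_len(nGenes)),
               chrom = chrom, strand = strand, tss = tss, tes = tes,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  new("SyntheticGenome", chromLengths = chromLengths, genes = genes,
      seed = as.integer(seed))
}

#' Specify planted enrichment regions
#'
#' Builds (and validates) the planted-peak table consumed by
#' [generateReads()]. Each row plants one enrichment region: reads inside
#' the `width`-bp window around `center` are drawn at `enrichment` times the
#' background density. `condition` controls which read sets see the peak:
#' `"stimulated"`, `"unstimulated"`, or `"both"`; for `"both"`,
#' `pairOffset` shifts the unstimulated copy's center (0 plants an unchanged
#' Basal pair, a large offset plants a Shift pair). `geneId` records which
#' gene the peak is planted for (ground truth only).
#'
#' @param chrom,center,enrichment,width,condition,pairOffset,geneId vectors
#'   recycled to a common length.
#' @return validated data.frame of planted peaks.
#' @export
plantedPeaks <- function(chrom, center, enrichment = 15, width = 300,
                         condition = "stimulated", pairOffset = 0,
                         geneId = NA_character_) {
  if (length(chrom) == 0L)
    return(data.frame(chrom = character(0), center = numeric(0),
                      enrichment = numeric(0), width = numeric(0),
                      condition = character(0), pairOffset = numeric(0),
                      geneId = character(0), stringsAsFactors = FALSE))
  spec <- data.frame(chrom = chrom, center = center,
                     enrichment = enrichment, width = width,
                     condition = condition, pairOffset = pairOffset,
                     geneId = geneId, stringsAsFactors = FALSE)
  if (any(spec$enrichment <= 1)) stop("enrichment factors must exceed 1")
  if (any(spec$width <= 0)) stop("peak widths must be positive")
  if (!all(spec$condition %in% c("stimulated", "unstimulated", "both")))
    stop("condition must be stimulated / unstimulated / both")
  spec
}

# realized peak windows for one condition (1-based inclusive)
.peakWindows <- function(peaks, condition) {
  keep <- if (condition == "input") character(0) else c(condition, "both")
  sel <- peaks[peaks$condition %in% keep, , drop = FALSE]
  if (!nrow(sel)) {
    sel$start <- numeric(0)
    sel$end <- numeric(0)
    return(sel)
  }
  centers <- sel$center +
    ifelse(sel$condition == "both" & condition == "unstimulated",
           sel$pairOffset, 0)
  sel$center <- centers
  sel$start <- centers - floor(sel$width / 2) + 1L
  sel$end <- sel$start + sel$width - 1L
  sel
}

#' Generate a mapped read set with planted enrichment
#'
#' Read starts are placed uniformly at the background density everywhere
#' except inside planted peak windows, where the density is multiplied by
#' the peak's enrichment factor. Exactly `nReads` reads are produced
#' (multinomial allocation over background and peak segments, uniform
#' placement within each); strands are random. The default `nReads` matches
#' the expected count at `backgroundDensity`,
#' i.e. `density * (genome size + extra peak mass)`.
#'
#' @param genome a [SyntheticGenome-class].
#' @param peaks data.frame from [plantedPeaks()] (may be empty /
#'   zero rows for an input-like sample).
#' @param condition `"stimulated"`, `"unstimulated"` or `"input"` -- selects
#'   which planted peaks apply (`"input"`: none).
#' @param backgroundDensity background reads per bp (> 0).
#' @param nReads total read count; default derived from the density.
#' @param seed integer seed; the same seed reproduces the read set exactly.
#' @param readLength read length recorded on the set (default 36).
#' @return a [MappedReadSet-class] sorted per chromosome.
#' @export
generateReads <- function(genome, peaks = plantedPeaks(character(0),
                                                       numeric(0)),
                          condition = c("stimulated", "unstimulated",
                                        "input"),
                          backgroundDensity = 0.01, nReads = NULL,
                          seed = 1L, readLength = 36L) {
  stopifnot(is(genome, "SyntheticGenome"))
  condition <- match.arg(condition)
  if (backgroundDensity <= 0) stop("backgroundDensity must be positive")
  lens <- chromLengths(genome)
  win <- .peakWindows(peaks, condition)
  if (nrow(win)) {
    if (!all(win$chrom %in% names(lens)))
      stop("invalid peak spec: unknown chromosome")
    if (any(win$start < 1 | win$end > lens[win$chrom]))
      stop("invalid peak spec: peak outside chromosome bounds")
    for (chr in unique(win$chrom)) {
      wc <- win[win$chrom == chr, , drop = FALSE]
      wc <- wc[order(wc$start), , drop = FALSE]
      if (nrow(wc) > 1L && any(wc$start[-1L] <= wc$end[-nrow(wc)]))
        stop("invalid peak spec: overlapping peak windows on ", chr)
    }
  }
  # segment table: per chromosome one background segment (complement of the
  # peak windows) plus one segment per peak window, weighted by density
  segs <- lapply(names(lens), function(chr) {
    wc <- win[win$chrom == chr, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    bgLen <- lens[[chr]] - sum(wc$width)
    rbind(data.frame(chrom = chr, start = NA_real_, end = NA_real_,
                     len = bgLen, weight = bgLen),
          if (nrow(wc)) data.frame(chrom = chr, start = wc$start,
                                   end = wc$end, len = wc$width,
                                   weight = wc$width * wc$enrichment))
  })
  segs <- do.call(rbind, segs)
  if (is.null(nReads)) nReads <- round(backgroundDensity * sum(segs$weight))
  if (nReads <= 0) stop("nReads must be positive")
  gr <- withr::with_seed(seed, {
    alloc <- as.vector(stats::rmultinom(1L, nReads,
                                        segs$weight / sum(segs$weight)))
    pos <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      k <- alloc[i]
      if (k == 0L) { pos[[i]] <- integer(0); next }
      if (is.na(segs$start[i])) {
        # background: draw offsets in the complement of the peak windows
        chr <- segs$chrom[i]
        wc <- win[win$chrom == chr, , drop = FALSE]
        wc <- wc[order(wc$start), , drop = FALSE]
        off <- sample.int(segs$len[i], k, replace = TRUE)
        if (nrow(wc)) {
          # map offsets through the gaps between windows
          gapStart <- c(1, wc$end + 1)
          gapEnd <- c(wc$start - 1, chromLengths(genome)[[chr]])
          gapLen <- gapEnd - gapStart + 1
          cum <- cumsum(c(0, gapLen[-length(gapLen)]))
          gi <- findInterval(off - 1, cumsum(gapLen), left.open = FALSE) + 1L
          pos[[i]] <- gapStart[gi] + (off - 1 - cum[gi])
        } else pos[[i]] <- off
      } else {
        pos[[i]] <- segs$start[i] + sample.int(segs$len[i], k,
                                               replace = TRUE) - 1L
      }
    }
    chrom <- rep(segs$chrom, lengths(pos))
    strand <- sample(c("+", "-"), nReads, replace = TRUE)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(unlist(pos), width = 1L),
                           strand = strand, seqlengths = lens)
  })
  MappedReadSet(gr, label = condition, readLength = readLength)
}

#' Generate a two-condition replicate expression matrix
#'
#' Log2-scale expression for every gene of the genome across
#' `2 * nReplicates` samples. Non-DE genes share the same mean in both
#' conditions; genes in `deGeneIds` differ by `log2Effect` in the stimulated
#' condition, with alternating sign (up, down, up, ...) in the order given.
#' Gaussian noise with `noiseSd` is added independently per sample
#' (`noiseSd = 0` reproduces the condition means exactly).
#'
#' @param genome a [SyntheticGenome-class] (or any object with gene ids via
#'   [geneModels()]).
#' @param deGeneIds gene ids planted as differentially expressed.
#' @param log2Effect effect magnitude in log2 units (default 2).
#' @param noiseSd Gaussian noise standard deviation (default 0.3).
#' @param nReplicates replicates per condition (>= 2, default 3).
#' @param seed integer seed.
#' @return list: `matrix` (genes x samples, columns unstimulated then
#'   stimulated), `groups` (factor per column), `deGenes` (the planted ids
#'   with their signed effects).
#' @export
generateExpression <- function(genome, deGeneIds = character(0),
                               log2Effect = 2, noiseSd = 0.3,
                               nReplicates = 3L, seed = 1L) {
  if (nReplicates < 2L) stop("need at least 2 replicates per condition")
  ids <- geneModels(genome)$gene_id
  unknown <- setdiff(deGeneIds, ids)
  if (length(unknown))
    stop("unknown gene id(s) in deGeneIds: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  n <- length(ids)
  effects <- stats::setNames(numeric(n), ids)
  if (length(deGeneIds))
    effects[deGeneIds] <- log2Effect * rep_len(c(1, -1), length(deGeneIds))
  mat <- withr::with_seed(seed, {
    base <- stats::runif(n, 6, 10)
    means <- cbind(matrix(base, n, nReplicates),
                   matrix(base + effects, n, nReplicates))
    means + matrix(stats::rnorm(n * 2L * nReplicates, 0, noiseSd),
                   n, 2L * nReplicates)
  })
  rownames(mat) <- ids
  colnames(mat) <- c(sprintf("unstimulated_%d", seq_len(nReplicates)),
                     sprintf("stimulated_%d", seq_len(nReplicates)))
  groups <- factor(rep(c("unstimulated", "stimulated"), each = nReplicates),
                   levels = c("unstimulated", "stimulated"))
  list(matrix = mat, groups = groups,
       deGenes = effects[deGeneIds])
}

#' Generate locus sequences with planted motif instances
#'
#' One i.i.d. background sequence per locus (lengths equal the locus
#' widths), with a motif instance sampled from the PWM's per-position
#' probabilities embedded at a random offset on a random strand in a random
#' `plantedFraction` subset of the sequences.
#'
#' @param loci `GRanges` of loci (their widths set the sequence lengths) or
#'   an integer vector of lengths.
#' @param pwm [PWMotif-class] to plant (`NULL` with `plantedFraction = 0`
#'   for pure background).
#' @param plantedFraction fraction of sequences receiving one instance.
#' @param seed integer seed.
#' @param background background nucleotide frequencies (default uniform).
#' @return `DNAStringSet`, with a logical `planted` metadata column.
#' @export
generateLocusSequences <- function(loci, pwm = NULL, plantedFraction = 0,
                                   seed = 1L, background = rep(0.25, 4)) {
  .checkProportion(plantedFraction, "plantedFraction")
  lens <- if (is(loci, "GRanges")) GenomicRanges::width(loci) else
    as.integer(loci)
  n <- length(lens)
  ids <- if (is(loci, "GRanges") && !is.null(names(loci))) names(loci) else
    sprintf("locus_%04d", seq_len(n))
  if (plantedFraction > 0 && is.null(pwm))
    stop("a PWM is required to plant motif instances")
  if (!is.null(pwm) && any(lens < motifLength(pwm)) && plantedFraction > 0)
    stop("motif longer than at least one locus")
  seqs <- withr::with_seed(seed, {
    planted <- logical(n)
    if (plantedFraction > 0) {
      planted[sample.int(n, round(plantedFraction * n))] <- TRUE
    }
    s <- vapply(seq_len(n), function(i) {
      nt <- sample(.BASES, lens[i], replace = TRUE, prob = background)
      if (planted[i]) {
        w <- motifLength(pwm)
        inst <- vapply(seq_len(w), function(j)
          sample(.BASES, 1L, prob = pwm@probs[, j]), character(1))
        if (stats::runif(1) < 0.5) {
          inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        }
        at <- sample.int(lens[i] - w + 1L, 1L)
        nt[at:(at + w - 1L)] <- inst
      }
      paste(nt, collapse = "")
    }, character(1))
    attr(s, "planted") <- planted
    s
  })
  out <- Biostrings::DNAStringSet(stats::setNames(as.character(seqs), ids))
  S4Vectors::mcols(out)$planted <- attr(seqs, "planted")
  out
}

#' Specify a planted-prognosis patient cohort
#'
#' Parameters of the synthetic cohort generator: two latent patient groups
#' that differ by `effectSize` (in units of the expression noise SD) in the
#' mean of the prognostic gene group, exponential survival with
#' `hazardRatio` between the groups, an exact planted censoring fraction
#' (uniform censoring times), and optionally a fraction of patients with
#' missing survival information (emulating cohorts where not every profiled
#' patient has follow-up).
#'
#' @param nPatients number of patients (default 153).
#' @param nGenes number of signature-candidate genes (default 187).
#' @param prognosticGenes indices of the planted prognostic gene group
#'   (default 1:49).
#' @param effectSize group separation in noise SDs (default 3).
#' @param baselineHazard hazard of the good-survival group per month
#'   (default `log(2) / 63`, i.e. median 63 months).
#' @param hazardRatio hazard ratio of the poor- vs good-survival group
#'   (> 0; default 2, i.e. medians about 31 vs 63 months).
#' @param censoringFraction fraction of patients censored (default 0.15).
#' @param missingSurvivalFraction fraction with survival set to `NA`
#'   (default 0).
#' @param seed integer seed.
#' @return validated list of class `PlantedCohortSpec`.
#' @export
plantedCohortSpec <- function(nPatients = 153L, nGenes = 187L,
                              prognosticGenes = 1:49, effectSize = 3,
                              baselineHazard = log(2) / 63,
                              hazardRatio = 2, censoringFraction = 0.15,
                              missingSurvivalFraction = 0, seed = 1L) {
  if (any(prognosticGenes < 1L) || any(prognosticGenes > nGenes))
    stop("prognostic gene indices must lie within 1..nGenes")
  if (hazardRatio <= 0) stop("hazardRatio must be positive")
  .checkProportion(censoringFraction, "censoringFraction")
  .checkProportion(missingSurvivalFraction, "missingSurvivalFraction")
  if (baselineHazard <= 0) stop("baselineHazard must be positive")
  structure(list(nPatients = as.integer(nPatients),
                 nGenes = as.integer(nGenes),
                 prognosticGenes = as.integer(prognosticGenes),
                 effectSize = effectSize, baselineHazard = baselineHazard,
                 hazardRatio = hazardRatio,
                 censoringFraction = censoringFraction,
                 missingSurvivalFraction = missingSurvivalFraction,
                 seed = as.integer(seed)),
            class = "PlantedCohortSpec")
}

#' Generate a synthetic patient cohort
#'
#' Patients are split into two equal-sized latent groups. Expression is unit
#' Gaussian noise; the poor-survival group's mean is raised by `effectSize`
#' on the prognostic genes. Survival times are exponential with the group's
#' hazard; an exact `censoringFraction` of patients is censored at a uniform
#' time before their event, and a `missingSurvivalFraction` gets `NA`
#' survival.
#'
#' @param spec a [plantedCohortSpec()].
#' @return a [CohortData-class]; `colData` includes the latent
#'   `planted_group` (1 = good survival, 2 = poor survival).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "PlantedCohortSpec"))
  n <- spec$nPatients
  g <- spec$nGenes
  withr::with_seed(spec$seed, {
    group <- sample(rep(1:2, length.out = n))
    mat <- matrix(stats::rnorm(g * n), g, n)
    mat[spec$prognosticGenes, group == 2L] <-
      mat[spec$prognosticGenes, group == 2L, drop = FALSE] + spec$effectSize
    rate <- spec$baselineHazard *
      ifelse(group == 2L, spec$hazardRatio, 1)
    time <- stats::rexp(n, rate)
    event <- rep(1, n)
    ncens <- round(spec$censoringFraction * n)
    if (ncens > 0L) {
      ci <- sample.int(n, ncens)
      time[ci] <- stats::runif(ncens, 0, time[ci])
      event[ci] <- 0
    }
    nmiss <- round(spec$missingSurvivalFraction * n)
    if (nmiss > 0L) {
      mi <- sample.int(n, nmiss)
      time[mi] <- NA
      event[mi] <- NA
    }
    rownames(mat) <- sprintf("gene_%03d", seq_len(g))
    colnames(mat) <- sprintf("patient_%03d", seq_len(n))
    surv <- data.frame(patient_id = colnames(mat), time_months = time,
                       event = event, planted_group = group,
                       stringsAsFactors = FALSE)
    CohortData(mat, surv,
               prognosticGenes = rownames(mat)[spec$prognosticGenes])
  })
}
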