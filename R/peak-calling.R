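#' @include AllGenerics.R
NULL

#' Bin mapped reads into fixed-width windows
#'
#' Counts read start positions in non-overlapping bins of `binWidth` bp per
#' chromosome. A read starting at 0-based position `s` falls into bin
#' `floor(s / binWidth)`; the trailing partial bin is kept, so every read is
#' counted exactly once.
#'
#' @param x a [MappedReadSet-class].
#' @param binWidth bin width in bp (default 300).
#' @return a [BinTrack-class].
#' @export
binReads <- function(x, binWidth = 300L) {
  stopifnot(is(x, "MappedReadSet"))
  binWidth <- as.integer(binWidth)
  if (binWidth < 1L) stop("binWidth must be positive")
  lens <- chromLengths(x)
  gr <- reads(x)
  starts0 <- split(GenomicRanges::start(gr) - 1L,
                   factor(as.character(GenomicRanges::seqnames(gr)),
                          levels = names(lens)))
  counts <- lapply(names(lens), function(chr) {
    nb <- as.integer(ceiling(lens[[chr]] / binWidth))
    tabulate(starts0[[chr]] %/% binWidth + 1L, nbins = nb)
  })
  names(counts) <- names(lens)
  new("BinTrack", binWidth = binWidth, counts = counts,
      chromLengths = lens, label = sampleLabel(x))
}

#' Construct a BinTrack from raw counts
#'
#' Mostly useful for tests and small worked examples; [binReads()] is the
#' usual entry point.
#'
#' @param counts named list of per-chromosome integer bin counts (a bare
#'   vector is taken as a single chromosome `chr1`).
#' @param binWidth bin width in bp.
#' @param chromLengths named chromosome lengths; defaults to
#'   `bins * binWidth`.
#' @param label sample label.
#' @return a [BinTrack-class].
#' @export
BinTrack <- function(counts, binWidth = 300L, chromLengths = NULL,
                     label = "track") {
  if (!is.list(counts)) counts <- list(chr1 = counts)
  counts <- lapply(counts, as.integer)
  if (is.null(chromLengths))
    chromLengths <- vapply(counts, length, integer(1)) * binWidth
  new("BinTrack", binWidth = as.integer(binWidth), counts = counts,
      chromLengths = stats::setNames(as.numeric(chromLengths),
                                     names(counts)),
      label = label)
}

#' Percentile-scoring enrichment threshold
#'
#' Returns the count threshold at a given percentile level, computed over the
#' nonzero bins of the track (genomes are mostly empty; zero bins carry no
#' signal information). The threshold is the smallest observed count `c` such
#' that the fraction of nonzero bins with count `>= c` is at most
#' `1 - percentileLevel`; if no observed count satisfies this (e.g. a
#' constant track), the maximal observed count is returned.
#'
#' @param track a [BinTrack-class].
#' @param percentileLevel acceptance level in (0, 1), e.g. 0.996.
#' @return integer count threshold.
#' @export
percentileThreshold <- function(track, percentileLevel = 0.996) {
  stopifnot(is(track, "BinTrack"))
  .checkProportion(percentileLevel, "percentileLevel",
                   open_lower = TRUE, open_upper = TRUE)
  cnt <- unlist(binCounts(track), use.names = FALSE)
  nz <- sort(cnt[cnt > 0L])
  if (!length(nz)) stop("all bins are zero: no signal to threshold")
  u <- unique(nz)
  fracGE <- (length(nz) - match(u, nz) + 1L) / length(nz)
  ok <- which(fracGE <= 1 - percentileLevel)
  if (length(ok)) u[ok[1L]] else max(nz)
}

# shared locus caller at a fixed count threshold; `scale` rescales the input
# track to the calling track's depth before the per-bin comparison
.callAtThreshold <- function(chip, input, threshold, minGap, level, condition) {
  w <- binWidth(chip)
  out <- lapply(names(binCounts(chip)), function(chr) {
    cc <- binCounts(chip)[[chr]]
    ic <- binCounts(input)[[chr]]
    it <- totalReads(input)
    scale <- if (it > 0) totalReads(chip) / it else 0
    ics <- ic * scale
    sig <- which(cc >= threshold & cc > ics)
    if (!length(sig)) return(NULL)
    run <- cumsum(c(1L, diff(sig) > minGap))
    L <- chromLengths(chip)[[chr]]
    do.call(rbind, lapply(split(sig, run), function(b) {
      bmax <- b[which.max(cc[b])]
      data.frame(chrom = chr,
                 start = (b[1L] - 1L) * w + 1L,
                 end = min(b[length(b)] * w, L),
                 summit = min((bmax - 1L) * w + ceiling(w / 2), L),
                 score = sum(cc[b]) - sum(ics[b]))
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    gr <- GenomicRanges::GRanges(
      seqinfo = GenomeInfoDb::Seqinfo(names(chromLengths(chip)),
                                      unname(chromLengths(chip))))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      summit = integer(0), score = numeric(0),
      level = numeric(0), condition = character(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start, out$end),
                               seqlengths = chromLengths(chip))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    summit = as.integer(out$summit), score = out$score,
    level = rep(level, nrow(out)), condition = rep(condition, nrow(out)))
  names(gr) <- NULL
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

# geometry compatibility check between two tracks
.checkGeometry <- function(a, b) {
  if (binWidth(a) != binWidth(b) ||
      !identical(names(binCounts(a)), names(binCounts(b))) ||
      !all(lengths(binCounts(a)) == lengths(binCounts(b))))
    stop("bin tracks must share bin width and chromosome geometry")
}

#' Call binding loci against an input control
#'
#' A bin is significant when its ChIP count reaches the percentile threshold
#' of the ChIP track *and* exceeds the depth-scaled input count (input counts
#' are multiplied by ChIP total / input total). Significant bins within
#' `minGap` bins of each other are merged into one locus. The locus summit is
#' the center of its maximum-count bin (leftmost on ties); the locus score is
#' the summed ChIP count minus the summed scaled input count.
#'
#' @param chip,input [BinTrack-class] objects with identical geometry.
#' @param percentileLevel acceptance level (default 0.996).
#' @param minGap maximal bin gap merged into one locus (default 1 = only
#'   adjacent significant bins merge).
#' @param condition label stored on each called locus.
#' @return a `GRanges` of loci (0-based half-open when exported as BED) with
#'   metadata columns `summit`, `score`, `level`, `condition`; sorted and
#'   non-overlapping.
#' @export
callLoci <- function(chip, input, percentileLevel = 0.996, minGap = 1L,
                     condition = sampleLabel(chip)) {
  stopifnot(is(chip, "BinTrack"), is(input, "BinTrack"))
  .checkGeometry(chip, input)
  thr <- percentileThreshold(chip, percentileLevel)
  .callAtThreshold(chip, input, thr, as.integer(minGap),
                   percentileLevel, condition)
}

#' Estimate the false discovery rate from simulated reads
#'
#' Places `nSimulatedReads` reads uniformly over the genome (the same number
#' as the observed ChIP library by default), bins them with the ChIP track's
#' geometry, and calls loci on the simulated track using the *same* count
#' thresholds derived from the observed ChIP track at each percentile level.
#' FDR(level) = simulated locus count / max(observed locus count, 1),
#' clipped to 1.
#'
#' @param chip,input [BinTrack-class] objects with identical geometry.
#' @param percentileLevels numeric vector of levels; reported tightest first.
#' @param nSimulatedReads simulated library size.
#' @param seed integer seed for read placement.
#' @param minGap as in [callLoci()].
#' @return data.frame with columns level, threshold, observed, simulated, fdr.
#' @export
estimateFdr <- function(chip, input,
                        percentileLevels = c(0.999, 0.996, 0.99, 0.95),
                        nSimulatedReads = totalReads(chip), seed = 1L,
                        minGap = 1L) {
  stopifnot(is(chip, "BinTrack"), is(input, "BinTrack"))
  .checkGeometry(chip, input)
  lens <- chromLengths(chip)
  w <- binWidth(chip)
  sim <- withr::with_seed(seed, {
    per <- as.vector(stats::rmultinom(1L, nSimulatedReads,
                                      lens / sum(lens)))
    counts <- lapply(seq_along(lens), function(i) {
      nb <- as.integer(ceiling(lens[[i]] / w))
      s0 <- sample.int(lens[[i]], per[i], replace = TRUE) - 1L
      tabulate(s0 %/% w + 1L, nbins = nb)
    })
    names(counts) <- names(lens)
    counts
  })
  simTrack <- new("BinTrack", binWidth = w, counts = sim,
                  chromLengths = lens, label = "simulated")
  lv <- sort(percentileLevels, decreasing = TRUE)
  rows <- lapply(lv, function(level) {
    thr <- percentileThreshold(chip, level)
    obs <- length(.callAtThreshold(chip, input, thr, as.integer(minGap),
                                   level, "observed"))
    nsim <- length(.callAtThreshold(simTrack, input, thr, as.integer(minGap),
                                    level, "simulated"))
    data.frame(level = level, threshold = thr, observed = obs,
               simulated = nsim, fdr = min(1, nsim / max(obs, 1L)))
  })
  do.call(rbind, rows)
}
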