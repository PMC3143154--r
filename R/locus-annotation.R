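#' @include AllGenerics.R
NULL

#' Assign binding loci to their nearest gene TSS
#'
#' Each locus is assigned to the gene whose transcription start site is
#' closest to the locus summit, provided that distance is within `window` bp;
#' otherwise it stays unassigned. Distances are signed in gene orientation:
#' negative means upstream of the TSS. Ties between equidistant genes are
#' broken by lower TSS coordinate, then lexicographic gene id.
#'
#' @param loci `GRanges` of loci with a `summit` metadata column (as returned
#'   by [callLoci()]).
#' @param genes gene model data.frame (columns gene_id, chrom, strand, tss,
#'   tes), e.g. from [geneModels()].
#' @param window maximal |summit - TSS| distance in bp (default 100000).
#' @param promoterWindow promoter half-width around the TSS (default 8000).
#' @return data.frame with one row per locus: locus_id, chrom, summit,
#'   gene_id (NA when unassigned), distance (signed bp, NA when unassigned),
#'   promoter (logical).
#' @export
assignToGenes <- function(loci, genes, window = 100000, promoterWindow = 8000) {
  stopifnot(is(loci, "GRanges"), "summit" %in% names(S4Vectors::mcols(loci)))
  chroms <- as.character(GenomicRanges::seqnames(loci))
  unknown <- setdiff(unique(chroms), unique(genes$chrom))
  if (length(unknown))
    stop("loci on chromosome(s) unknown to the gene annotation: ",
         paste(unknown, collapse = ", "))
  summit <- S4Vectors::mcols(loci)$summit
  n <- length(loci)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == chroms[i], , drop = FALSE]
    if (!nrow(g)) next
    d_abs <- abs(summit[i] - g$tss)
    ord <- order(d_abs, g$tss, g$gene_id)
    best <- ord[1L]
    if (d_abs[best] <= window) {
      gene_id[i] <- g$gene_id[best]
      d <- summit[i] - g$tss[best]
      dist[i] <- if (g$strand[best] == "-") -d else d
    }
  }
  data.frame(locus_id = if (!is.null(names(loci)) && any(nzchar(names(loci))))
               names(loci)
             else sprintf("locus_%04d", seq_len(n)),
             chrom = chroms, summit = summit, gene_id = gene_id,
             distance = dist,
             promoter = !is.na(dist) & abs(dist) <= promoterWindow,
             stringsAsFactors = FALSE)
}

#' Summarise a locus-to-gene assignment
#'
#' Counts and percentages (half-up, one decimal) of loci assigned within the
#' gene window and of loci in the promoter window. Both percentages use all
#' loci as the denominator.
#'
#' @param assignments data.frame from [assignToGenes()].
#' @return one-row data.frame: n_loci, n_assigned, pct_assigned, n_promoter,
#'   pct_promoter.
#' @export
assignmentSummary <- function(assignments) {
  n <- nrow(assignments)
  na <- sum(!is.na(assignments$gene_id))
  np <- sum(assignments$promoter)
  data.frame(n_loci = n, n_assigned = na,
             pct_assigned = roundHalfUp(100 * na / n, 1),
             n_promoter = np,
             pct_promoter = roundHalfUp(100 * np / n, 1))
}

#' Histogram of signed TSS-relative distances
#'
#' Bins the signed summit-to-TSS distances of the gene-assigned loci;
#' unassigned loci are excluded. Bin `b` covers
#' `[b * binWidth, (b + 1) * binWidth)`.
#'
#' @param assignments data.frame from [assignToGenes()].
#' @param binWidth histogram bin width in bp (default 10000).
#' @return data.frame with columns bin_start, bin_end, count.
#' @export
tssDistanceHistogram <- function(assignments, binWidth = 10000) {
  if (!nrow(assignments)) stop("no assignments supplied")
  d <- assignments$distance[!is.na(assignments$distance)]
  b <- floor(d / binWidth)
  tab <- table(b)
  idx <- as.numeric(names(tab))
  data.frame(bin_start = idx * binWidth,
             bin_end = (idx + 1) * binWidth,
             count = as.integer(tab))
}

#' Classify binding loci into cross-condition binding patterns
#'
#' For each gene, its stimulated and unstimulated loci are paired greedily,
#' nearest summit distance first (ties by leftmost stimulated summit, then
#' leftmost unstimulated summit). A pair at distance at most `shiftThreshold`
#' bp is a `Basal` call (unchanged binding); a pair farther apart is a
#' `Shift`. Leftover loci become `StimulatedOnly` / `UnstimulatedOnly`.
#' Every gene-assigned locus contributes to exactly one pattern call.
#'
#' @param stim,unstim assignment data.frames from [assignToGenes()] for the
#'   stimulated and unstimulated conditions.
#' @param shiftThreshold Basal-vs-Shift summit distance cutoff in bp
#'   (default 1000).
#' @return data.frame: gene_id, category, stim_summit, unstim_summit,
#'   distance (NA for single-condition calls).
#' @export
classifyPatterns <- function(stim, unstim, shiftThreshold = 1000) {
  s <- stim[!is.na(stim$gene_id), , drop = FALSE]
  u <- unstim[!is.na(unstim$gene_id), , drop = FALSE]
  genes <- sort(unique(c(s$gene_id, u$gene_id)))
  calls <- lapply(genes, function(g) {
    ss <- sort(s$summit[s$gene_id == g])
    us <- sort(u$summit[u$gene_id == g])
    rows <- list()
    while (length(ss) && length(us)) {
      d <- abs(outer(ss, us, "-"))
      hit <- which(d == min(d), arr.ind = TRUE)
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
      dd <- d[hit[1L], hit[2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g,
        category = if (dd <= shiftThreshold) "Basal" else "Shift",
        stim_summit = ss[hit[1L]], unstim_summit = us[hit[2L]],
        distance = dd, stringsAsFactors = FALSE)
      ss <- ss[-hit[1L]]
      us <- us[-hit[2L]]
    }
    for (x in ss)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, category = "StimulatedOnly", stim_summit = x,
        unstim_summit = NA_real_, distance = NA_real_,
        stringsAsFactors = FALSE)
    for (x in us)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, category = "UnstimulatedOnly", stim_summit = NA_real_,
        unstim_summit = x, distance = NA_real_, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Per-condition binding-pattern counts and percentages
#'
#' Counts the loci of one condition in each pattern category that applies to
#' it (`Basal`, `Shift`, and the matching `*Only` category), with percentages
#' of that condition's gene-assigned loci, rounded half-up to one decimal.
#'
#' @param calls data.frame from [classifyPatterns()].
#' @param condition `"stimulated"` or `"unstimulated"`.
#' @return data.frame: category, count, percent; total loci as attribute
#'   `"total"`.
#' @export
patternSummary <- function(calls, condition = c("stimulated", "unstimulated")) {
  condition <- match.arg(condition)
  if (!nrow(calls)) stop("no pattern calls supplied")
  own <- if (condition == "stimulated") "StimulatedOnly" else "UnstimulatedOnly"
  col <- if (condition == "stimulated") "stim_summit" else "unstim_summit"
  sub <- calls[!is.na(calls[[col]]), , drop = FALSE]
  cats <- c(own, "Shift", "Basal")
  count <- vapply(cats, function(cc) sum(sub$category == cc), integer(1))
  total <- sum(count)
  out <- data.frame(category = cats, count = count,
                    percent = roundHalfUp(100 * count / total, 1),
                    row.names = NULL)
  attr(out, "total") <- total
  out
}
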