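#' @include AllGenerics.R
NULL

#' Replicate differential-expression calls
#'
#' Per gene, an equal-variance two-sample Student t-test between the two
#' replicate groups of a log-scale expression matrix. The log2 fold change is
#' mean(treatment) - mean(reference). A gene is flagged differentially
#' expressed when `|log2FC| > fcThreshold` and `p < pThreshold` (deliberately
#' liberal defaults, no multiple-testing correction; a Benjamini-Hochberg
#' column is included for information only).
#'
#' @param mat numeric matrix, genes x samples, log2 scale (set
#'   `logTransform = TRUE` for linear-scale input).
#' @param groups factor/character of length `ncol(mat)` with exactly two
#'   levels.
#' @param treatment the group level whose mean enters the fold change
#'   positively (default: the second level).
#' @param fcThreshold absolute log2 fold-change cutoff (default 0.5).
#' @param pThreshold p-value cutoff (default 0.1).
#' @param logTransform log2-transform the matrix first (default FALSE).
#' @return data.frame: gene_id, mean_reference, mean_treatment, log2fc, p,
#'   padj, de.
#' @export
differentialExpression <- function(mat, groups, treatment = NULL,
                                   fcThreshold = 0.5, pThreshold = 0.1,
                                   logTransform = FALSE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels")
  if (any(table(groups) < 2L))
    stop("each condition needs at least 2 replicates")
  if (length(groups) != ncol(mat))
    stop("'groups' must match the matrix columns")
  if (logTransform) mat <- log2(mat)
  if (is.null(treatment)) treatment <- levels(groups)[2L]
  reference <- setdiff(levels(groups), treatment)
  a <- mat[, groups == treatment, drop = FALSE]
  b <- mat[, groups == reference, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  na <- ncol(a); nb <- ncol(b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df = na + nb - 2, lower.tail = FALSE)
  # degenerate rows: zero spread in both groups
  degen <- se == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  log2fc <- ma - mb
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_len(nrow(mat)))
  data.frame(gene_id = ids, mean_reference = mb, mean_treatment = ma,
             log2fc = log2fc, p = p, padj = stats::p.adjust(p, "BH"),
             de = abs(log2fc) > fcThreshold & p < pThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect differential expression with binding-target genes
#'
#' Three-way partition of the gene universe: differentially expressed genes
#' without a binding locus, locus-bearing genes without differential
#' expression, and genes with both. Fold-change and p thresholds may be
#' re-applied here (on the stored statistics) to derive stricter partitions
#' from the same results table.
#'
#' @param results data.frame from [differentialExpression()].
#' @param targetGeneIds character vector of locus-bearing gene ids.
#' @param fcThreshold,pThreshold optional re-thresholding; `NULL` keeps the
#'   stored `de` flag.
#' @return list with character vectors `deOnly`, `locusOnly`, `deAndLocus`
#'   and a one-row `summary` data.frame (counts plus the percentage of DE
#'   genes that carry a locus, half-up one decimal).
#' @export
integrateTargets <- function(results, targetGeneIds, fcThreshold = NULL,
                             pThreshold = NULL) {
  de <- if (is.null(fcThreshold) && is.null(pThreshold)) {
    results$de
  } else {
    fc <- if (is.null(fcThreshold)) 0.5 else fcThreshold
    pt <- if (is.null(pThreshold)) 0.1 else pThreshold
    abs(results$log2fc) > fc & results$p < pt
  }
  deGenes <- results$gene_id[de]
  inTarget <- results$gene_id %in% targetGeneIds
  deAndLocus <- results$gene_id[de & inTarget]
  deOnly <- results$gene_id[de & !inTarget]
  locusOnly <- results$gene_id[!de & inTarget]
  nDE <- length(deGenes)
  list(deOnly = deOnly, locusOnly = locusOnly, deAndLocus = deAndLocus,
       summary = data.frame(
         n_de = nDE, n_de_only = length(deOnly),
         n_locus_only = length(locusOnly),
         n_de_and_locus = length(deAndLocus),
         pct_de_with_locus =
           roundHalfUp(100 * length(deAndLocus) / max(nDE, 1L), 1)))
}

#' Stricter-threshold variant of the integration partition
#'
#' [integrateTargets()] with the p-value cutoff tightened (default 0.05, same
#' fold-change cutoff), recomputed from the stored per-gene statistics.
#'
#' @inheritParams integrateTargets
#' @param pThreshold stricter p cutoff (default 0.05).
#' @param fcThreshold fold-change cutoff (default 0.5).
#' @return as [integrateTargets()].
#' @export
strictVariant <- function(results, targetGeneIds, pThreshold = 0.05,
                          fcThreshold = 0.5) {
  integrateTargets(results, targetGeneIds, fcThreshold = fcThreshold,
                   pThreshold = pThreshold)
}
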