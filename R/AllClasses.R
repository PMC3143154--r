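#' @import methods
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels keepSeqlevels
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

#' Mapped sequencing reads for one ChIP-seq sample
#'
#' Holds uniquely mapped single-end read start positions as width-one
#' [GenomicRanges::GRanges] with strand, plus the sample label and the read
#' length (positions are sufficient for binning; no fragment model is used).
#'
#' @slot reads `GRanges` of read start positions (width 1), with `seqlengths`.
#' @slot label single character sample label.
#' @slot readLength integer read length in bp (metadata only).
#' @export
setClass("MappedReadSet",
  slots = c(reads = "GRanges", label = "character", readLength = "integer"))

setValidity("MappedReadSet", function(object) {
  gr <- object@reads
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl)))
    return("all chromosomes must have a defined seqlength")
  if (length(gr)) {
    if (any(GenomicRanges::start(gr) < 1L))
      return("read positions must be >= 1")
    bad <- GenomicRanges::start(gr) >
      sl[as.character(GenomicRanges::seqnames(gr))]
    if (any(bad))
      return("read positions exceed chromosome bounds")
    chr <- as.integer(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    if (is.unsorted(chr) || any(diff(pos) < 0 & diff(chr) == 0L))
      return("reads must be sorted by chromosome and position")
  }
  if (length(object@label) != 1L) return("label must be a single string")
  if (object@readLength < 1L) return("readLength must be positive")
  TRUE
})

#' Construct a MappedReadSet
#'
#' @param reads a `GRanges` of read positions (widths are collapsed to the
#'   start coordinate); must carry `seqlengths`.
#' @param label sample label.
#' @param readLength read length in bp (default 36).
#' @return a [MappedReadSet-class] object, sorted.
#' @export
MappedReadSet <- function(reads, label = "sample", readLength = 36L) {
  reads <- GenomicRanges::resize(reads, width = 1L, fix = "start",
                                 ignore.strand = TRUE)
  new("MappedReadSet",
      reads = BiocGenerics::sort(reads, ignore.strand = TRUE),
      label = label, readLength = as.integer(readLength))
}

#' Fixed-width bin counts over a genome
#'
#' Per-chromosome counts of read starts in non-overlapping fixed-width bins;
#' the trailing partial bin is kept.
#'
#' @slot binWidth integer bin width in bp.
#' @slot counts named list of integer vectors, one per chromosome.
#' @slot chromLengths named numeric chromosome lengths in bp.
#' @slot label source sample label.
#' @export
setClass("BinTrack",
  slots = c(binWidth = "integer", counts = "list",
            chromLengths = "numeric", label = "character"))

setValidity("BinTrack", function(object) {
  if (object@binWidth < 1L) return("binWidth must be positive")
  if (!identical(names(object@counts), names(object@chromLengths)))
    return("counts and chromLengths must name the same chromosomes")
  nb <- ceiling(object@chromLengths / object@binWidth)
  if (!all(lengths(object@counts) == nb))
    return("each chromosome needs ceiling(length / binWidth) bins")
  if (any(unlist(object@counts, use.names = FALSE) < 0))
    return("bin counts must be non-negative")
  TRUE
})

#' A synthetic genome with gene models
#'
#' A small diploid-agnostic genome description used by the data generators:
#' chromosome lengths plus strand-aware gene models (the TSS is the 5' end of
#' the gene in its own orientation, so `tss < tes` on `+` and `tss > tes`
#' on `-`).
#'
#' @slot chromLengths named numeric chromosome lengths (bp).
#' @slot genes data.frame with columns gene_id, chrom, strand, tss, tes.
#' @slot seed integer seed the genome was generated from.
#' @export
setClass("SyntheticGenome",
  slots = c(chromLengths = "numeric", genes = "data.frame", seed = "integer"))

setValidity("SyntheticGenome", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("gene ids must be unique")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!all(g$chrom %in% names(object@chromLengths)))
    return("gene chromosomes must appear in chromLengths")
  lim <- object@chromLengths[g$chrom]
  if (any(pmin(g$tss, g$tes) < 1) || any(pmax(g$tss, g$tes) > lim))
    return("gene intervals must lie within chromosome bounds")
  plus <- g$strand == "+"
  if (any(g$tss[plus] >= g$tes[plus]) || any(g$tss[!plus] <= g$tes[!plus]))
    return("need tss < tes on '+' strand and tss > tes on '-' strand")
  TRUE
})

#' A position weight matrix with background model
#'
#' Column-stochastic per-position nucleotide probabilities (rows A, C, G, T)
#' after pseudocount regularisation, together with the background frequencies
#' used for log-odds scoring.
#'
#' @slot id motif identifier.
#' @slot probs 4 x L probability matrix, rows named A/C/G/T.
#' @slot background length-4 background nucleotide frequencies.
#' @slot pseudocount pseudocount added per matrix cell before normalisation.
#' @export
setClass("PWMotif",
  slots = c(id = "character", probs = "matrix",
            background = "numeric", pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  p <- object@probs
  if (!identical(rownames(p), c("A", "C", "G", "T")))
    return("probs rows must be named A, C, G, T")
  if (ncol(p) < 4L) return("motif length must be >= 4")
  if (any(abs(colSums(p) - 1) > 1e-8))
    return("each probs column must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-8)
    return("background must be 4 frequencies summing to 1")
  if (any(object@background <= 0)) return("background must be positive")
  TRUE
})

#' A hub-TF regulatory network
#'
#' Hub transcription factors (motifs enriched in target loci relative to
#' matched random background), regulated gene nodes with their expression
#' direction, and TF-to-gene edges supported by motif hits, optionally with
#' permutation p-values.
#'
#' @slot hubs data.frame of the hub screen (motif, hit fractions, p, padj).
#' @slot nodes data.frame with columns id, type ("hub"/"gene"), direction.
#' @slot edges data.frame with columns tf, gene, hits, p.
#' @slot scoreFraction scan threshold as a fraction of the maximal log-odds.
#' @export
setClass("RegulatoryNetwork",
  slots = c(hubs = "data.frame", nodes = "data.frame",
            edges = "data.frame", scoreFraction = "numeric"))

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (!all(e$tf %in% object@nodes$id) || !all(e$gene %in% object@nodes$id))
      return("every edge endpoint must be a node")
  }
  TRUE
})

#' A patient cohort with expression and survival
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay is the
#' (log-scale) expression matrix, genes x patients, and whose `colData`
#' carries survival time in months, the event indicator (1 = death observed,
#' 0 = censored) and, for synthetic cohorts, the planted latent patient
#' group. Patients with missing survival (`NA`) are retained in the matrix
#' and dropped by the survival procedures.
#'
#' @slot prognosticGenes character vector of planted prognostic gene ids
#'   (empty for real cohorts).
#' @export
setClass("CohortData",
  contains = "SummarizedExperiment",
  slots = c(prognosticGenes = "character"))

setValidity("CohortData", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time_months", "event") %in% names(cd)))
    return("colData must contain time_months and event")
  t_ok <- is.na(cd$time_months) | cd$time_months > 0
  e_ok <- is.na(cd$event) | cd$event %in% c(0, 1)
  if (!all(t_ok)) return("time_months must be positive (or NA)")
  if (!all(e_ok)) return("event must be 0/1 (or NA)")
  if (!all(object@prognosticGenes %in% rownames(object)))
    return("prognosticGenes must be row names of the expression matrix")
  TRUE
})
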