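#' @include AllClasses.R
NULL

#' Accessors for TFscape classes
#'
#' Small accessor family: `reads()` returns the read `GRanges`,
#' `sampleLabel()` the sample label, `totalReads()` the read or binned-read
#' count, `chromLengths()` the named chromosome lengths, `binWidth()` and
#' `binCounts()` the bin geometry and per-chromosome counts, `geneModels()`
#' the gene table of a synthetic genome, `motifLength()` / `motifId()` PWM
#' properties, and `hubTFs()` / `networkEdges()` / `networkNodes()` the parts
#' of a regulatory network. `survivalData()` extracts the survival columns of
#' a cohort as a plain data.frame and `expressionMatrix()` its assay.
#'
#' @param x an object of the documented classes.
#' @return see details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))
#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setGeneric("hubTFs", function(x) standardGeneric("hubTFs"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))
#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
#' @rdname accessors
#' @export
setGeneric("prognosticGenes", function(x) standardGeneric("prognosticGenes"))

#' @rdname accessors
#' @export
setMethod("reads", "MappedReadSet", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "MappedReadSet", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("totalReads", "MappedReadSet", function(x) length(x@reads))
#' @rdname accessors
#' @export
setMethod("chromLengths", "MappedReadSet",
          function(x) GenomeInfoDb::seqlengths(x@reads))

#' @rdname accessors
#' @export
setMethod("binWidth", "BinTrack", function(x) x@binWidth)
#' @rdname accessors
#' @export
setMethod("binCounts", "BinTrack", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("chromLengths", "BinTrack", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("totalReads", "BinTrack",
          function(x) sum(unlist(x@counts, use.names = FALSE)))
#' @rdname accessors
#' @export
setMethod("sampleLabel", "BinTrack", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("chromLengths", "SyntheticGenome", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("geneModels", "SyntheticGenome", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("motifLength", "PWMotif", function(x) ncol(x@probs))
#' @rdname accessors
#' @export
setMethod("motifId", "PWMotif", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("hubTFs", "RegulatoryNetwork", function(x) x@hubs)
#' @rdname accessors
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("survivalData", "CohortData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(patient_id = rownames(cd), as.data.frame(cd),
             row.names = NULL, stringsAsFactors = FALSE)
})
#' @rdname accessors
#' @export
setMethod("expressionMatrix", "CohortData",
          function(x) SummarizedExperiment::assay(x, "exprs"))
#' @rdname accessors
#' @export
setMethod("prognosticGenes", "CohortData", function(x) x@prognosticGenes)

setMethod("show", "MappedReadSet", function(object) {
  cat(sprintf("MappedReadSet '%s': %d reads (%d bp) on %d chromosome(s)\n",
              object@label, length(object@reads), object@readLength,
              length(GenomeInfoDb::seqlengths(object@reads))))
})

setMethod("show", "BinTrack", function(object) {
  cat(sprintf(
    "BinTrack '%s': %d bp bins, %d bins over %d chromosome(s), %d reads\n",
    object@label, object@binWidth,
    sum(lengths(object@counts)), length(object@counts),
    totalReads(object)))
})

setMethod("show", "SyntheticGenome", function(object) {
  cat(sprintf(
    "SyntheticGenome: %d chromosome(s) (%.2f Mb), %d gene models, seed %d\n",
    length(object@chromLengths), sum(object@chromLengths) / 1e6,
    nrow(object@genes), object@seed))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s': length %d, consensus %s\n", object@id,
              ncol(object@probs),
              paste(c("A", "C", "G", "T")[apply(object@probs, 2, which.max)],
                    collapse = "")))
})

setMethod("show", "RegulatoryNetwork", function(object) {
  nh <- sum(object@nodes$type == "hub")
  ng <- sum(object@nodes$type == "gene")
  cat(sprintf("RegulatoryNetwork: %d hub TF(s), %d gene(s), %d edge(s)\n",
              nh, ng, nrow(object@edges)))
  if (nrow(object@edges) && !all(is.na(object@edges$p)))
    cat(sprintf("  permutation p attached to %d edge(s)\n",
                sum(!is.na(object@edges$p))))
})

setMethod("show", "CohortData", function(object) {
  sd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "CohortData: %d genes x %d patients (%d with complete survival)\n",
    nrow(object), ncol(object),
    sum(!is.na(sd$time_months) & !is.na(sd$event))))
  if (length(object@prognosticGenes))
    cat(sprintf("  planted prognostic group: %d genes\n",
                length(object@prognosticGenes)))
})
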