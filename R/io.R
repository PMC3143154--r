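#' @include AllGenerics.R
NULL

#' Read and write mapped reads as BED
#'
#' `readMappedReads()` imports a 6-column BED file of read positions (via
#' rtracklayer) into a [MappedReadSet-class]; `writeMappedReads()` exports
#' one. BED coordinates are 0-based half-open on disk and converted
#' automatically.
#'
#' @param path BED file path.
#' @param chromLengths named numeric chromosome lengths.
#' @param label sample label.
#' @param x a [MappedReadSet-class].
#' @return `readMappedReads()`: a [MappedReadSet-class]; the writer returns
#'   the path invisibly.
#' @export
readMappedReads <- function(path, chromLengths, label = basename(path)) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read BED files")
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
  GenomeInfoDb::seqlengths(gr) <- chromLengths
  MappedReadSet(gr, label = label)
}

#' @rdname readMappedReads
#' @export
writeMappedReads <- function(x, path) {
  gr <- reads(x)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::start(gr),
                   name = ".", score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called loci as BED6 + summit and score columns
#'
#' Columns: chrom, start (0-based), end, name, score (rounded enrichment
#' score), strand (`.`), summit (0-based), raw score.
#'
#' @param loci `GRanges` from [callLoci()].
#' @param path output path.
#' @export
writeLociBed <- function(loci, path) {
  mc <- S4Vectors::mcols(loci)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                   start = GenomicRanges::start(loci) - 1L,
                   end = GenomicRanges::end(loci),
                   name = sprintf("locus_%04d", seq_along(loci)),
                   score = round(mc$score), strand = ".",
                   summit = mc$summit - 1L, raw_score = mc$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write gene annotation tables
#'
#' Plain TSV with header: gene_id, chrom, strand, tss, tes.
#'
#' @param genes gene model data.frame.
#' @param path file path.
#' @export
writeGeneTable <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tes")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an expression or cohort matrix as TSV
#'
#' Genes in rows (first column `gene_id`), sample ids in the header row.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @export
writeMatrixTSV <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Write and read cohort survival tables
#'
#' TSV with header: patient_id, time_months, event (plus any extra columns).
#'
#' @param survival survival data.frame.
#' @param path file path.
#' @export
writeSurvivalTSV <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurvivalTSV
#' @export
readSurvivalTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a regulatory network as SIF plus attributes
#'
#' The SIF file has one `TF regulates gene` line per edge (loadable by
#' standard graph viewers); the attribute TSV carries the gene direction,
#' hit count and permutation p per edge.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param sifPath SIF output path.
#' @param attrPath optional attribute TSV path.
#' @export
writeNetworkSIF <- function(network, sifPath, attrPath = NULL) {
  e <- networkEdges(network)
  lines <- if (nrow(e)) paste(e$tf, "regulates", e$gene, sep = "\t")
           else character(0)
  writeLines(lines, sifPath)
  if (!is.null(attrPath)) {
    nd <- networkNodes(network)
    attr <- data.frame(tf = e$tf, gene = e$gene,
                       direction = nd$direction[match(e$gene, nd$id)],
                       hits = e$hits, p = e$p)
    utils::write.table(attr, attrPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sifPath)
}

#' @rdname writeNetworkSIF
#' @param path SIF file path.
#' @return `readNetworkSIF()`: data.frame with columns tf, relation, gene.
#' @export
readNetworkSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(tf = character(0), relation = character(0),
                      gene = character(0)))
  parts <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(tf = parts[, 1L], relation = parts[, 2L], gene = parts[, 3L],
             stringsAsFactors = FALSE)
}

#' Write locus sequences as FASTA
#'
#' @param seqs a `DNAStringSet`.
#' @param path file path.
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeFastaSeqs
#' @export
readFastaSeqs <- function(path) {
  Biostrings::readDNAStringSet(path)
}
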