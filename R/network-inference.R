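#' @include motif.R
NULL

#' Screen a PWM library for hub transcription factors
#'
#' For every motif, counts target and background sequences containing at
#' least one hit and tests enrichment with a one-sided Fisher exact test on
#' the 2x2 table (with hit / without hit, targets / background). Motifs
#' significant after Benjamini-Hochberg correction at `alpha` *and* with a
#' larger hit fraction in targets than in background are flagged as hub TFs;
#' the table is ranked by adjusted then raw p. The background set is
#' expected to be length- and size-matched to the targets (the synthetic
#' generator guarantees this).
#'
#' @param targetSeqs,backgroundSeqs character vectors or `DNAStringSet`s.
#' @param pwms list of [PWMotif-class] objects.
#' @param scoreFraction scan threshold (default 0.8 of maximal log-odds).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame ranked by adjusted p: motif, target_hits, target_n,
#'   background_hits, background_n, target_frac, background_frac, p, padj,
#'   hub (logical).
#' @export
findHubTFs <- function(targetSeqs, backgroundSeqs, pwms,
                       scoreFraction = 0.8, alpha = 0.05) {
  if (!length(pwms)) stop("empty PWM library")
  if (is(pwms, "PWMotif")) pwms <- list(pwms)
  tn <- length(targetSeqs)
  bn <- length(backgroundSeqs)
  rows <- lapply(pwms, function(p) {
    th <- sum(.hasHit(targetSeqs, p, scoreFraction))
    bh <- sum(.hasHit(backgroundSeqs, p, scoreFraction))
    pv <- stats::fisher.test(matrix(c(th, tn - th, bh, bn - bh), nrow = 2L),
                             alternative = "greater")$p.value
    data.frame(motif = motifId(p), target_hits = th, target_n = tn,
               background_hits = bh, background_n = bn,
               target_frac = th / tn, background_frac = bh / bn, p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  out$hub <- out$padj < alpha & out$target_frac > out$background_frac
  out <- out[order(out$padj, out$p, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wire a hub-TF regulatory network by PWM scanning
#'
#' An edge TF -> gene is present when the hub's PWM has at least one hit in
#' at least one of the gene's binding-locus sequences. Gene nodes carry the
#' regulation direction (up/down) from the differential-expression results.
#' Genes without any locus sequence are skipped with a warning. Edge
#' p-values are `NA` until [testNetworkEdges()] is run.
#'
#' @param hubScreen data.frame from [findHubTFs()] (its `hub` rows are used),
#'   or a character vector of motif ids.
#' @param pwms list of [PWMotif-class], named by motif id.
#' @param geneLoci named list: gene id -> character vector / `DNAStringSet`
#'   of its binding-locus sequences. Restrict to the genes with both a locus
#'   and differential expression.
#' @param expression data.frame from [differentialExpression()] supplying
#'   `log2fc` per gene.
#' @param scoreFraction scan threshold (default 0.8).
#' @return a [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(hubScreen, pwms, geneLoci, expression,
                         scoreFraction = 0.8) {
  hubIds <- if (is.character(hubScreen)) hubScreen
            else hubScreen$motif[hubScreen$hub]
  hubTab <- if (is.data.frame(hubScreen))
    hubScreen[hubScreen$hub, , drop = FALSE] else
    data.frame(motif = hubIds, stringsAsFactors = FALSE)
  missingPwm <- setdiff(hubIds, names(pwms))
  if (length(missingPwm))
    stop("no PWM supplied for hub(s): ", paste(missingPwm, collapse = ", "))
  emptySeq <- lengths(geneLoci) == 0L
  if (any(emptySeq)) {
    warning("skipping gene(s) without locus sequence: ",
            paste(names(geneLoci)[emptySeq], collapse = ", "))
    geneLoci <- geneLoci[!emptySeq]
  }
  genes <- names(geneLoci)
  dirn <- expression$log2fc[match(genes, expression$gene_id)]
  nodes <- rbind(
    data.frame(id = hubIds, type = rep("hub", length(hubIds)),
               direction = rep(NA_character_, length(hubIds)),
               stringsAsFactors = FALSE),
    data.frame(id = genes, type = rep("gene", length(genes)),
               direction = ifelse(is.na(dirn), NA_character_,
                                  ifelse(dirn >= 0, "up", "down")),
               stringsAsFactors = FALSE))
  edges <- list()
  for (tf in hubIds) {
    for (g in genes) {
      h <- .hitCount(geneLoci[[g]], pwms[[tf]], scoreFraction)
      if (h > 0L)
        edges[[length(edges) + 1L]] <- data.frame(
          tf = tf, gene = g, hits = h, p = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(0), gene = character(0),
               hits = integer(0), p = numeric(0))
  new("RegulatoryNetwork", hubs = hubTab, nodes = nodes, edges = edges,
      scoreFraction = scoreFraction)
}

#' Permutation test for one network edge
#'
#' Null model: each locus sequence of the gene is shuffled preserving its
#' dinucleotide composition, the shuffled set is rescanned, and the total
#' hit count is compared with the observed one. The p-value uses the add-one
#' estimator `p = (1 + #{permutation count >= observed}) / (1 + n)`, so
#' `p >= 1 / (n + 1)` always, and an observed count of 0 gives p = 1.
#'
#' @param seqs the gene's locus sequences (character or `DNAStringSet`).
#' @param pwm the edge TF's [PWMotif-class].
#' @param scoreFraction scan threshold (default 0.8).
#' @param nPermutations number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: p, observed, permuted (integer vector of null counts).
#' @export
permutationEdgeTest <- function(seqs, pwm, scoreFraction = 0.8,
                                nPermutations = 1000L, seed = 1L) {
  if (nPermutations < 100L) stop("use at least 100 permutations")
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  observed <- .hitCount(seqs, pwm, scoreFraction)
  permuted <- withr::with_seed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      sh <- vapply(seqs, dinucShuffle, character(1), USE.NAMES = FALSE)
      .hitCount(sh, pwm, scoreFraction)
    }, integer(1))
  })
  list(p = (1 + sum(permuted >= observed)) / (1 + nPermutations),
       observed = observed, permuted = permuted)
}

#' Attach permutation p-values to every edge of a network
#'
#' Runs [permutationEdgeTest()] per edge with per-edge seeds derived
#' deterministically from `seed`.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param pwms named list of [PWMotif-class].
#' @param geneLoci as in [buildNetwork()].
#' @param scoreFraction scan threshold; defaults to the network's.
#' @param nPermutations permutations per edge.
#' @param seed global integer seed.
#' @return the network with `edges$p` filled in.
#' @export
testNetworkEdges <- function(network, pwms, geneLoci,
                             scoreFraction = network@scoreFraction,
                             nPermutations = 1000L, seed = 1L) {
  e <- networkEdges(network)
  if (nrow(e)) {
    e$p <- vapply(seq_len(nrow(e)), function(i) {
      permutationEdgeTest(geneLoci[[e$gene[i]]], pwms[[e$tf[i]]],
                          scoreFraction, nPermutations,
                          seed = stageSeed(seed, paste0(e$tf[i], e$gene[i]))
                          )$p
    }, numeric(1))
  }
  network@edges <- e
  network
}
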