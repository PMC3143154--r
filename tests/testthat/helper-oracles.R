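# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive re-implementation of the documented contract, kept
# structurally different from the package code it checks.

# smallest count with tail fraction (over nonzero bins) <= 1 - level,
# found by scanning every candidate count
oraclePercentile <- function(counts, level) {
  nz <- counts[counts > 0]
  best <- NA
  for (c in sort(unique(nz))) {
    if (mean(nz >= c) <= 1 - level) { best <- c; break }
  }
  if (is.na(best)) max(nz) else best
}

# single-chromosome locus caller: enumerate bins, merge by linear scan
oracleLoci <- function(chip, input, w, chromLen, thr, minGap = 1L) {
  scale <- if (sum(input) > 0) sum(chip) / sum(input) else 0
  sig <- which(chip >= thr & chip > input * scale)
  if (!length(sig)) return(NULL)
  groups <- list()
  cur <- sig[1]
  for (b in sig[-1]) {
    if (b - cur[length(cur)] <= minGap) cur <- c(cur, b)
    else { groups[[length(groups) + 1]] <- cur; cur <- b }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(b) {
    bmax <- b[which.max(chip[b])]
    data.frame(start = (b[1] - 1) * w + 1,
               end = min(b[length(b)] * w, chromLen),
               summit = min((bmax - 1) * w + ceiling(w / 2), chromLen),
               score = sum(chip[b]) - sum(input[b] * scale))
  }))
}

# all-pairs nearest-TSS assignment
oracleAssign <- function(summits, chroms, genes, window) {
  out <- data.frame(gene_id = NA_character_, distance = NA_real_)
  out <- out[rep(1, length(summits)), ]
  for (i in seq_along(summits)) {
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != chroms[i]) next
      d <- abs(summits[i] - genes$tss[j])
      if (is.null(best) || d < best$d ||
          (d == best$d && (genes$tss[j] < best$tss ||
                           (genes$tss[j] == best$tss &&
                            genes$gene_id[j] < best$id))))
        best <- list(d = d, id = genes$gene_id[j], tss = genes$tss[j],
                     strand = genes$strand[j])
    }
    if (!is.null(best) && best$d <= window) {
      out$gene_id[i] <- best$id
      d <- summits[i] - best$tss
      out$distance[i] <- if (best$strand == "-") -d else d
    }
  }
  rownames(out) <- NULL
  out
}

# greedy nearest-first pairing for one gene, full-matrix rescan each step
oraclePairCategories <- function(ss, us, thr) {
  ss <- sort(ss); us <- sort(us)
  cats <- character(0)
  while (length(ss) > 0 && length(us) > 0) {
    bestd <- Inf; bi <- bj <- NA
    for (i in seq_along(ss)) for (j in seq_along(us)) {
      d <- abs(ss[i] - us[j])
      if (d < bestd) { bestd <- d; bi <- i; bj <- j }
    }
    cats <- c(cats, if (bestd <= thr) "Basal" else "Shift")
    ss <- ss[-bi]; us <- us[-bj]
  }
  c(cats, rep("StimulatedOnly", length(ss)),
    rep("UnstimulatedOnly", length(us)))
}

# exhaustive window-by-window PWM scan (both strands, skip N windows)
oracleScan <- function(sequence, probs, background, scoreFraction) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  S <- log2(probs / background)
  maxS <- sum(apply(S, 2, max))
  nt <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(S)
  hits <- NULL
  if (length(nt) >= w) {
    for (o in 1:(length(nt) - w + 1)) {
      win <- nt[o:(o + w - 1)]
      if (!all(win %in% bases)) next
      sF <- sum(S[cbind(match(win, bases), 1:w)])
      winR <- rev(unname(comp[win]))
      sR <- sum(S[cbind(match(winR, bases), 1:w)])
      if (sF >= scoreFraction * maxS - 1e-9)
        hits <- rbind(hits, data.frame(offset = o, strand = "+",
                                       score = sF))
      if (sR >= scoreFraction * maxS - 1e-9)
        hits <- rbind(hits, data.frame(offset = o, strand = "-",
                                       score = sR))
    }
  }
  hits
}

# naive O(n^3) average-linkage agglomeration down to k clusters
oracleAvgLinkage <- function(d, k) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  D <- d
  diag(D) <- Inf
  while (length(members) > k) {
    idx <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf
    members <- members[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  lab <- integer(n)
  for (g in seq_along(members)) lab[members[[g]]] <- g
  lab
}

# textbook two-group log-rank arithmetic (deaths before censorings at ties)
oracleLogrank <- function(time, event, grp) {
  g <- as.integer(factor(grp))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & g == 1)
    n <- sum(time >= t)
    d1 <- sum(time == t & event == 1 & g == 1)
    d <- sum(time == t & event == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# hand product-limit estimator at the distinct event times
oracleKM <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# same-partition check up to label renaming
samePartition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(data.frame(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# quick uniform-background read fixture on one chromosome
makeReadSet <- function(starts, chromLen = NULL, chrom = "chr1",
                        label = "chip") {
  if (is.null(chromLen)) chromLen <- max(starts) + 100
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, width = 1L),
    strand = "+",
    seqlengths = stats::setNames(chromLen, chrom))
  MappedReadSet(gr, label = label)
}
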