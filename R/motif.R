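#' @include AllGenerics.R
NULL

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Builds a [PWMotif-class] from a count (or probability) matrix. A
#' pseudocount is added to every cell before column normalisation so that
#' log-odds scores stay finite on sparse matrices.
#'
#' @param counts 4 x L numeric matrix; rows in A, C, G, T order (row names
#'   are set if missing).
#' @param id motif identifier.
#' @param background length-4 background nucleotide frequencies
#'   (default uniform).
#' @param pseudocount added per cell before normalisation (default 0.01).
#' @return a [PWMotif-class].
#' @export
PWMotif <- function(counts, id = "motif",
                    background = rep(0.25, 4), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM matrices need 4 rows (A, C, G, T)")
  rownames(counts) <- .BASES
  p <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  new("PWMotif", id = id, probs = p, background = background,
      pseudocount = pseudocount)
}

#' Build a sharp PWM from a consensus string
#'
#' Convenience constructor: each column gives weight `strength` to the
#' consensus base and `(1 - strength) / 3` to the others (before the
#' pseudocount). `strength = 1` yields a degenerate-free consensus matrix.
#'
#' @param consensus character string over A/C/G/T.
#' @param strength per-position consensus probability (default 1).
#' @param id motif identifier (default the consensus itself).
#' @inheritParams PWMotif
#' @return a [PWMotif-class].
#' @export
pwmFromConsensus <- function(consensus, strength = 1, id = consensus,
                             background = rep(0.25, 4), pseudocount = 0.01) {
  nt <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(nt %in% .BASES)) stop("consensus must be over A/C/G/T")
  m <- matrix((1 - strength) / 3 * 100, nrow = 4L, ncol = length(nt),
              dimnames = list(.BASES, NULL))
  m[cbind(match(nt, .BASES), seq_along(nt))] <- strength * 100
  PWMotif(m, id = id, background = background, pseudocount = pseudocount)
}

#' Read a JASPAR-style PWM library
#'
#' Parses a plain-text motif library: a `>id` header line followed by four
#' count rows in A, C, G, T order. Rows may be bare whitespace-separated
#' numbers or the bracketed JASPAR form `A [ 4 19 0 ... ]`.
#'
#' @param path file path.
#' @inheritParams PWMotif
#' @return named list of [PWMotif-class] objects.
#' @export
readPWMLibrary <- function(path, background = rep(0.25, 4),
                           pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' motif headers found in ", path)
  pwms <- lapply(seq_along(hdr), function(i) {
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[(hdr[i] + 1L):to]
    if (length(block) < 4L) stop("motif ", id, " needs 4 count rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", id, " has ragged count rows")
    PWMotif(do.call(rbind, rows), id = id, background = background,
            pseudocount = pseudocount)
  })
  names(pwms) <- vapply(pwms, motifId, character(1))
  pwms
}

#' Write a PWM library in the same JASPAR-style format
#'
#' @param pwms list of [PWMotif-class] objects.
#' @param path output file path.
#' @export
writePWMLibrary <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", motifId(p)), con)
    m <- round(p@probs * 100, 2)
    for (i in 1:4)
      writeLines(paste(.BASES[i], "[", paste(m[i, ], collapse = " "), "]"),
                 con)
  }
  invisible(path)
}

# encode a sequence as integer codes 1..4 (NA for anything else, incl. N)
.encodeSeq <- function(sequence) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  match(strsplit(toupper(sequence), "")[[1L]], .BASES)
}

# log2-odds score matrix of a PWMotif
.logOdds <- function(pwm) log2(pwm@probs / pwm@background)

#' Scan a sequence with a PWM on both strands
#'
#' Computes the log2-odds score of every window on the forward and reverse
#' strand and reports windows scoring at least `scoreFraction` of the
#' maximal attainable log-odds. Windows containing `N` (or any non-ACGT
#' character) are skipped. A sequence shorter than the motif yields an empty
#' hit list.
#'
#' @param sequence character string or `DNAString`.
#' @param pwm a [PWMotif-class].
#' @param scoreFraction hit threshold as a fraction of the maximal log-odds
#'   (in (0, 1], default 0.8).
#' @param seqId sequence id copied into the result.
#' @return data.frame: seq_id, offset (1-based window start on the forward
#'   sequence), strand, score, frac.
#' @export
scanPWM <- function(sequence, pwm, scoreFraction = 0.8, seqId = "seq") {
  stopifnot(is(pwm, "PWMotif"))
  .checkProportion(scoreFraction, "scoreFraction", open_lower = TRUE)
  S <- .logOdds(pwm)
  maxScore <- sum(apply(S, 2L, max))
  if (maxScore <= 0)
    stop("PWM '", motifId(pwm), "' has no positive maximal log-odds score")
  code <- .encodeSeq(sequence)
  w <- ncol(S)
  n <- length(code)
  empty <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      frac = numeric(0))
  if (n < w) return(empty)
  windowScores <- function(cd) {
    sc <- numeric(n - w + 1L)
    for (j in seq_len(w)) sc <- sc + S[cd[j:(n - w + j)], j]
    sc
  }
  fw <- windowScores(code)
  rc <- 5L - rev(code)                     # reverse complement codes
  rv <- windowScores(rc)
  thr <- scoreFraction * maxScore - 1e-9
  hf <- which(!is.na(fw) & fw >= thr)
  hr <- which(!is.na(rv) & rv >= thr)
  out <- rbind(
    if (length(hf)) data.frame(seq_id = seqId, offset = hf, strand = "+",
                               score = fw[hf], frac = fw[hf] / maxScore),
    if (length(hr)) data.frame(seq_id = seqId, offset = n - w - hr + 2L,
                               strand = "-", score = rv[hr],
                               frac = rv[hr] / maxScore))
  if (is.null(out)) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# count hits of a pwm in a set of sequences (character vector/DNAStringSet)
.hitCount <- function(seqs, pwm, scoreFraction) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  sum(vapply(seqs, function(s)
    nrow(scanPWM(s, pwm, scoreFraction)), integer(1), USE.NAMES = FALSE))
}

.hasHit <- function(seqs, pwm, scoreFraction) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  vapply(seqs, function(s) nrow(scanPWM(s, pwm, scoreFraction)) > 0L,
         logical(1), USE.NAMES = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle that exactly preserves the dinucleotide (and therefore
#' mononucleotide) composition, via the Altschul-Erickson method: the
#' dinucleotide transitions form a multigraph, a random Eulerian path with
#' the original first and last residue is sampled, and the shuffled sequence
#' is read off that path. Draws from the current RNG stream.
#'
#' @param sequence character string or `DNAString`.
#' @return character string of the same length and dinucleotide content.
#' @export
dinucShuffle <- function(sequence) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  if (n < 3L) return(sequence)
  sym <- unique(chars)
  code <- match(chars, sym)
  sL <- code[n]
  adj <- split(code[-1L], code[-n])          # outgoing edge targets
  vkeys <- as.integer(names(adj))
  # sample a "last edge" per non-terminal vertex until they form a tree
  # oriented toward the terminal vertex (rejection sampling)
  repeat {
    last <- rep(NA_integer_, length(sym))
    for (v in vkeys) {
      if (v == sL) next
      x <- adj[[as.character(v)]]
      last[v] <- x[sample.int(length(x), 1L)]
    }
    ok <- TRUE
    for (v in vkeys) {
      if (v == sL) next
      cur <- v
      for (step in seq_len(length(sym) + 1L)) {
        cur <- last[cur]
        if (is.na(cur)) break
        if (cur == sL) break
      }
      if (is.na(cur) || cur != sL) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # permute the remaining edges; reserved last edges go last
  edgeOrder <- vector("list", length(sym))
  for (v in vkeys) {
    x <- adj[[as.character(v)]]
    if (!is.na(last[v])) {
      drop1 <- match(last[v], x)
      x <- x[-drop1]
    }
    x <- if (length(x)) x[sample.int(length(x))] else integer(0)
    if (!is.na(last[v])) x <- c(x, last[v])
    edgeOrder[[v]] <- x
  }
  # walk the Eulerian path
  out <- integer(n)
  out[1L] <- code[1L]
  ptr <- rep(1L, length(sym))
  cur <- code[1L]
  for (i in 2:n) {
    nxt <- edgeOrder[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(sym[out], collapse = "")
}
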