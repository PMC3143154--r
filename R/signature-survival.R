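#' @include AllGenerics.R
NULL

#' Construct a CohortData object
#'
#' @param exprs numeric matrix, genes x patients, log scale.
#' @param survival data.frame with columns patient_id, time_months, event
#'   (and optionally more, e.g. a stage label); rows match the matrix
#'   columns by patient_id.
#' @param prognosticGenes planted prognostic gene ids (synthetic cohorts).
#' @return a [CohortData-class].
#' @export
CohortData <- function(exprs, survival, prognosticGenes = character(0)) {
  stopifnot(is.matrix(exprs), all(c("patient_id", "time_months", "event")
                                  %in% names(survival)))
  survival <- survival[match(colnames(exprs), survival$patient_id), ,
                       drop = FALSE]
  if (any(is.na(survival$patient_id)))
    stop("every expression column needs a row in 'survival'")
  cd <- S4Vectors::DataFrame(survival[setdiff(names(survival), "patient_id")],
                             row.names = survival$patient_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("CohortData", se, prognosticGenes = as.character(prognosticGenes))
}

#' Mean-center each gene of a log-expression matrix
#'
#' Subtracts the row mean from every gene so each row averages zero;
#' constant rows become all-zero.
#'
#' @param mat numeric matrix, genes x samples.
#' @return the centered matrix.
#' @export
meanCenter <- function(mat) {
  sweep(mat, 1L, rowMeans(mat), "-")
}

#' Agglomerative clustering with Pearson correlation distance
#'
#' Hierarchical clustering of matrix rows (genes) or columns (patients) with
#' distance `1 - Pearson correlation` and average linkage, cut to exactly
#' `k` groups.
#'
#' @param mat numeric matrix, genes x patients.
#' @param axis `"genes"` (rows) or `"patients"` (columns).
#' @param k number of groups (default 4).
#' @return list of class `ClusterPartition`: labels (named integer vector),
#'   hclust object, k, metric, linkage.
#' @export
clusterItems <- function(mat, axis = c("genes", "patients"), k = 4L) {
  axis <- match.arg(axis)
  items <- if (axis == "genes") mat else t(mat)
  if (nrow(items) < k)
    stop("need at least k = ", k, " items to form k groups")
  sds <- apply(items, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant ", axis, " under correlation distance: ",
         paste(utils::head(rownames(items)[sds == 0], 5), collapse = ", "),
         " -- jitter or drop them first")
  d <- stats::as.dist(1 - stats::cor(t(items)))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, k = k,
                 metric = "pearson", linkage = "average",
                 axis = axis),
            class = "ClusterPartition")
}

#' @export
print.ClusterPartition <- function(x, ...) {
  cat(sprintf("ClusterPartition: %d %s in %d groups (1 - Pearson, %s linkage)\n",
              length(x$labels), x$axis, x$k, x$linkage))
  print(table(group = x$labels))
  invisible(x)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates with right censoring (deaths processed before
#' censorings at tied times, the standard convention), per group. The median
#' is the smallest time at which the curve drops to 0.5 or below, `NA` if
#' never reached. Subjects with missing time or event are dropped.
#'
#' @param times survival times (months).
#' @param events event indicators (1 = death observed, 0 = censored).
#' @param groups group label per subject.
#' @return list of class `SurvivalResult`: `curves` (data.frame group, time,
#'   surv, n_risk, n_event, n_censor) and `medians` (named numeric).
#' @export
kmEstimate <- function(times, events, groups = rep("all", length(times))) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  groups <- as.character(groups[keep])
  if (!length(times)) stop("no subjects with complete survival information")
  if (any(table(groups) < 1L)) stop("every group needs at least one subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(unique(groups), length(smry$time))
         else sub("^groups=", "", as.character(smry$strata))
  curves <- data.frame(group = grp, time = smry$time, surv = smry$surv,
                       n_risk = smry$n.risk, n_event = smry$n.event,
                       n_censor = smry$n.censor, stringsAsFactors = FALSE)
  medians <- vapply(split(curves, curves$group), function(cv) {
    hit <- which(cv$surv <= 0.5)
    if (length(hit)) cv$time[min(hit)] else NA_real_
  }, numeric(1))
  structure(list(curves = curves, medians = medians,
                 n = as.vector(table(groups))),
            class = "SurvivalResult")
}

#' @export
print.SurvivalResult <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  for (g in names(x$medians))
    cat(sprintf("  group %s: median %s months\n", g,
                ifelse(is.na(x$medians[g]), "not reached",
                       format(x$medians[g]))))
  if (!is.null(x$logrank_p))
    cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
                x$logrank_stat, x$logrank_p))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom; p from the
#' chi-square upper tail. A likelihood-ratio variant (from a Cox fit on the
#' group indicator) is available as an option. Subjects with missing
#' survival are dropped.
#'
#' @param times,events,groups as in [kmEstimate()]; exactly two groups.
#' @param method `"logrank"` (default) or `"likelihood-ratio"`.
#' @return list: statistic, p, method.
#' @export
logrankTest <- function(times, events, groups,
                        method = c("logrank", "likelihood-ratio")) {
  method <- match.arg(method)
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) != 2L)
    stop("log-rank test needs exactly two non-empty groups")
  if (method == "logrank") {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    stat <- sd$chisq
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  } else {
    cx <- survival::coxph(survival::Surv(times, events) ~ groups)
    stat <- 2 * diff(cx$loglik)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  list(statistic = unname(stat), p = unname(p), method = method)
}

#' Double-clustering gene-signature scan with survival evaluation
#'
#' Candidate genes are clustered into `kGene` groups (1 - Pearson, average
#' linkage, on the mean-centered matrix). For each gene group, the patients
#' are re-clustered into `kPatient` groups on that group's sub-matrix, and
#' every pair of patient groups is compared by log-rank test on the patients
#' with complete survival. The gene group attaining the smallest pairwise
#' log-rank p is reported as the signature. Note the selection over gene
#' groups and patient-group pairs is not multiplicity-corrected; the
#' reported p is a selection statistic, echoed as such in the output.
#'
#' @param cohort a [CohortData-class].
#' @param candidateGenes gene ids to scan (default: all rows).
#' @param kGene,kPatient group counts (defaults 4).
#' @return list: geneGroups (ClusterPartition), perGroup (list with patient
#'   partition, pairwise log-rank table, best pair and p, KM medians),
#'   selected (gene group id), selected_genes, best_p, note.
#' @export
signatureScan <- function(cohort, candidateGenes = rownames(cohort),
                          kGene = 4L, kPatient = 4L) {
  stopifnot(is(cohort, "CohortData"))
  missing <- setdiff(candidateGenes, rownames(cohort))
  if (length(missing))
    stop("candidate genes absent from the cohort matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  mat <- meanCenter(expressionMatrix(cohort)[candidateGenes, , drop = FALSE])
  sv <- survivalData(cohort)
  geneGroups <- clusterItems(mat, "genes", k = kGene)
  perGroup <- lapply(seq_len(kGene), function(g) {
    sub <- mat[names(geneGroups$labels)[geneGroups$labels == g], ,
               drop = FALSE]
    if (nrow(sub) < 2L || kPatient < 2L || ncol(sub) < kPatient)
      return(list(patientGroups = NULL, pairwise = NULL,
                  best_p = NA_real_, note = "no contrast"))
    pg <- clusterItems(sub, "patients", k = kPatient)
    lab <- pg$labels
    complete <- !is.na(sv$time_months) & !is.na(sv$event)
    pairs <- utils::combn(sort(unique(lab)), 2L)
    tests <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      sel <- complete & lab %in% c(g1, g2)
      if (length(unique(lab[sel])) < 2L)
        return(data.frame(group1 = g1, group2 = g2,
                          statistic = NA_real_, p = NA_real_))
      lt <- logrankTest(sv$time_months[sel], sv$event[sel], lab[sel])
      data.frame(group1 = g1, group2 = g2,
                 statistic = lt$statistic, p = lt$p)
    })
    pw <- do.call(rbind, tests)
    best <- which.min(pw$p)
    km <- kmEstimate(sv$time_months[complete], sv$event[complete],
                     lab[complete])
    list(patientGroups = pg, pairwise = pw,
         best_pair = c(pw$group1[best], pw$group2[best]),
         best_p = pw$p[best], km = km)
  })
  bp <- vapply(perGroup, function(x) x$best_p, numeric(1))
  selected <- which.min(bp)
  list(geneGroups = geneGroups, perGroup = perGroup,
       selected = selected,
       selected_genes =
         names(geneGroups$labels)[geneGroups$labels == selected],
       best_p = bp[selected],
       note = paste("best_p is minimised over gene groups and patient-group",
                    "pairs; it is a selection statistic, not a corrected",
                    "p-value"))
}

#' Random gene-set survival control
#'
#' Draws a random gene set of the signature's size, disjoint from the
#' excluded genes, re-clusters the patients on it and reports the best
#' pairwise log-rank p -- the negative control for a signature's survival
#' separation.
#'
#' @param cohort a [CohortData-class].
#' @param signatureSize number of genes to draw (> 0).
#' @param excludedGenes gene ids the draw must avoid (the signature itself).
#' @param kPatient patient group count (default 4).
#' @param seed integer seed (same seed, same draw).
#' @return list: genes, patientGroups, pairwise, best_p.
#' @export
randomSignatureControl <- function(cohort, signatureSize, excludedGenes,
                                   kPatient = 4L, seed = 1L) {
  stopifnot(is(cohort, "CohortData"))
  if (signatureSize < 1L) stop("signatureSize must be positive")
  pool <- setdiff(rownames(cohort), excludedGenes)
  if (length(pool) < signatureSize)
    stop("not enough non-excluded genes to draw from")
  genes <- withr::with_seed(seed, sample(pool, signatureSize))
  mat <- meanCenter(expressionMatrix(cohort)[genes, , drop = FALSE])
  pg <- clusterItems(mat, "patients", k = kPatient)
  sv <- survivalData(cohort)
  lab <- pg$labels
  complete <- !is.na(sv$time_months) & !is.na(sv$event)
  pairs <- utils::combn(sort(unique(lab)), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    sel <- complete & lab %in% c(g1, g2)
    if (length(unique(lab[sel])) < 2L)
      return(data.frame(group1 = g1, group2 = g2, statistic = NA_real_,
                        p = NA_real_))
    lt <- logrankTest(sv$time_months[sel], sv$event[sel], lab[sel])
    data.frame(group1 = g1, group2 = g2, statistic = lt$statistic, p = lt$p)
  }))
  list(genes = genes, patientGroups = pg, pairwise = pw,
       best_p = min(pw$p, na.rm = TRUE))
}
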