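test_that("meanCenter zeroes every row mean and matches the sweep oracle", {
  expect_equal(meanCenter(matrix(c(1, 2, 3), 1))[1, ], c(-1, 0, 1))
  set.seed(12)
  m <- matrix(rnorm(200), 20, 10)
  cm <- meanCenter(m)
  expect_true(all(abs(rowMeans(cm)) < 1e-12))
  expect_equal(cm, m - rowMeans(m) %*% t(rep(1, 10)))
  expect_equal(meanCenter(matrix(5, 2, 4)), matrix(0, 2, 4))
})

test_that("clusterItems recovers correlation blocks and handles edge cases", {
  set.seed(13)
  base <- rnorm(12)
  blockA <- t(replicate(5, base + rnorm(12, 0, 0.05)))
  blockB <- t(replicate(5, -base + rnorm(12, 0, 0.05)))
  m <- rbind(blockA, blockB)
  rownames(m) <- sprintf("it%02d", 1:10)
  cp <- clusterItems(m, "genes", k = 2)
  expect_true(samePartition(cp$labels, rep(1:2, each = 5)))

  cpn <- clusterItems(m, "genes", k = 10)
  expect_equal(sort(unique(cpn$labels)), 1:10)    # singletons

  m2 <- rbind(m, const = rep(1, 12))
  expect_error(clusterItems(m2, "genes", k = 2), "constant")
})

test_that("clusterItems matches a naive average-linkage oracle on planted blocks", {
  set.seed(14)
  centers <- matrix(rnorm(4 * 15), 4, 15)
  m <- do.call(rbind, lapply(1:4, function(b)
    t(replicate(7, centers[b, ] + rnorm(15, 0, 0.3)))))
  rownames(m) <- sprintf("g%02d", 1:28)
  cp <- clusterItems(m, "genes", k = 4)
  d <- 1 - cor(t(m))
  oracle <- oracleAvgLinkage(d, 4)
  expect_true(samePartition(cp$labels, oracle))
})

test_that("kmEstimate reproduces hand product-limit arithmetic", {
  # all censored -> flat curve, median never reached
  r0 <- kmEstimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(r0$curves$surv == 1))
  expect_true(is.na(r0$medians))

  # times 1,2,3 all events -> 2/3, 1/3, 0
  r1 <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(r1$curves$surv, c(2/3, 1/3, 0))
  expect_equal(unname(r1$medians), 2)

  # censoring at t = 2: risk-set arithmetic against the hand oracle
  r2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  o2 <- oracleKM(c(1, 2, 3), c(1, 0, 1))
  ev <- r2$curves[r2$curves$n_event > 0, ]
  expect_equal(ev$surv, o2$surv)
  # the curve before the censoring time is unchanged by the censoring
  expect_equal(r2$curves$surv[r2$curves$time == 1],
               r1$curves$surv[r1$curves$time == 1])
  expect_true(all(diff(r2$curves$surv) <= 1e-12))

  expect_error(kmEstimate(numeric(0), numeric(0)), "no subjects")
})

test_that("logrankTest agrees with textbook arithmetic and is label-symmetric", {
  t1 <- c(3, 5, 7, 9, 11); t2 <- c(2, 4, 6, 8, 10)
  tm <- c(t1, t2); ev <- rep(1, 10); gp <- rep(c("a", "b"), each = 5)
  got <- logrankTest(tm, ev, gp)
  exp <- oracleLogrank(tm, ev, gp)
  expect_equal(got$statistic, exp$statistic, tolerance = 1e-9)
  expect_equal(got$p, exp$p, tolerance = 1e-9)
  swapped <- logrankTest(tm, ev, rev(gp))
  expect_equal(got$statistic, swapped$statistic, tolerance = 1e-9)

  # identical survival in both groups -> statistic 0, p 1
  same <- logrankTest(rep(c(1, 2, 3), 2), rep(1, 6),
                      rep(c("x", "y"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # with censoring, against the oracle, over random fixtures
  for (s in 1:5) {
    set.seed(s)
    tm <- round(rexp(16, 0.1), 3); ev <- rbinom(16, 1, 0.7)
    gp <- rep(1:2, each = 8)
    if (sum(ev) == 0) next
    got <- logrankTest(tm, ev, gp)
    exp <- oracleLogrank(tm, ev, gp)
    expect_equal(got$statistic, exp$statistic, tolerance = 1e-9)
  }
  expect_error(logrankTest(c(1, 2), c(1, 1), c("a", "a")), "two")
  lr <- logrankTest(tm, ev, gp, method = "likelihood-ratio")
  expect_true(lr$p > 0 && lr$p <= 1)
})

test_that("signatureScan selects the planted prognostic group", {
  sp <- plantedCohortSpec(nPatients = 60, nGenes = 80,
                          prognosticGenes = 1:20, effectSize = 3,
                          hazardRatio = 4, censoringFraction = 0.1,
                          seed = 21)
  co <- generateCohort(sp)
  scan <- signatureScan(co, kGene = 4, kPatient = 4)
  planted <- prognosticGenes(co)
  expect_gte(length(intersect(scan$selected_genes, planted)) /
               length(planted), 0.8)
  expect_lt(scan$best_p, 0.05)
  expect_match(scan$note, "selection")

  # k_patient = 1 -> no contrast, no test
  scan1 <- signatureScan(co, kGene = 4, kPatient = 1)
  expect_true(all(vapply(scan1$perGroup, function(x) is.na(x$best_p),
                         logical(1))))

  expect_error(signatureScan(co, candidateGenes = "nope"), "absent")
})

test_that("patients with missing survival are excluded from the tests", {
  sp <- plantedCohortSpec(nPatients = 80, nGenes = 60,
                          prognosticGenes = 1:15, effectSize = 3,
                          hazardRatio = 4, censoringFraction = 0.1,
                          missingSurvivalFraction = 0.2, seed = 22)
  co <- generateCohort(sp)
  sv <- survivalData(co)
  expect_equal(sum(is.na(sv$time_months)), 16L)
  scan <- signatureScan(co, kGene = 3, kPatient = 3)
  expect_true(is.finite(scan$best_p))
})

test_that("randomSignatureControl draws reproducibly and validates input", {
  sp <- plantedCohortSpec(nPatients = 50, nGenes = 60,
                          prognosticGenes = 1:10, seed = 23)
  co <- generateCohort(sp)
  r1 <- randomSignatureControl(co, 10, prognosticGenes(co), seed = 5)
  r2 <- randomSignatureControl(co, 10, prognosticGenes(co), seed = 5)
  expect_identical(r1$genes, r2$genes)
  expect_length(intersect(r1$genes, prognosticGenes(co)), 0)
  expect_error(randomSignatureControl(co, 0, character(0)), "positive")
  expect_error(randomSignatureControl(co, 100, prognosticGenes(co)),
               "not enough")
})
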