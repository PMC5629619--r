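test_that("AUC follows the Mann-Whitney formulation with tie credit", {
  expect_equal(aucScore(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(aucScore(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  # label inversion complements the AUC
  s <- c(0.3, 0.9, 0.1, 0.5, 0.5)
  l <- c(0, 1, 0, 1, 0)
  expect_equal(aucScore(s, l) + aucScore(s, 1 - l), 1)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the brute-force pairwise oracle on random data", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    expect_equal(aucScore(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("MAUC is the arithmetic mean and reproduces the printed summaries", {
  expect_equal(round(mauc(c(0.686, 0.689, 0.696, 0.695, 0.699)), 3), 0.693)
  expect_equal(round(mauc(c(0.850, 0.828, 0.821, 0.850, 0.842)), 3), 0.838)
  expect_equal(mauc(rep(0.7, 4)), 0.7)
  expect_equal(mauc(c(0.6, 0.8)), mauc(c(0.8, 0.6)))
  expect_error(mauc(numeric(0)), "no AUC")
})

test_that("reduction schedule yields nested seeded subsets of the right sizes", {
  sizes <- c(482L, 478L, 473L, 468L, 463L)
  runs <- reductionRuns(482, sizes, seed = 4)
  expect_identical(lengths(runs), sizes)
  expect_identical(runs[[1]], 1:482)
  for (i in 2:5) expect_true(all(runs[[i]] %in% runs[[i - 1]]))
  expect_identical(reductionRuns(482, sizes, seed = 4), runs)
  expect_false(identical(reductionRuns(482, sizes, seed = 5)[[2]], runs[[2]]))

  expect_identical(reductionRuns(10, 10), list(1:10))
  expect_error(reductionRuns(10, c(10, 10, 8)), "decreasing")
  expect_error(reductionRuns(10, c(9, 8)), "full training size")
})

test_that("Wilcoxon signed-rank reproduces the printed cross-table p-value", {
  a1 <- c(0.878, 0.864, 0.871, 0.857, 0.871,   # A1+SVR+L, both cohorts
          0.668, 0.669, 0.665, 0.663, 0.656)
  b  <- c(0.835, 0.814, 0.800, 0.821, 0.835,   # B+SVR+L
          0.613, 0.609, 0.622, 0.628, 0.632)
  w <- wilcoxonSignedRank(a1, b)
  expect_equal(w$statistic, 55)
  expect_equal(round(w$p.value, 4), 0.0051)
  # the no-continuity-correction arithmetic: z = (55 - 27.5)/sqrt(96.25)
  expect_equal(w$p.value, 2 * pnorm(-(55 - 27.5) / sqrt(96.25)),
               tolerance = 1e-12)
  # two-tailed p is symmetric under swapping the pair
  expect_equal(wilcoxonSignedRank(b, a1)$p.value, w$p.value)
})

test_that("Wilcoxon handles degenerate and tied inputs", {
  a <- c(1, 2, 3, 4)
  d <- wilcoxonSignedRank(a, a)
  expect_true(d$degenerate)
  expect_equal(d$p.value, 1)
  # zero differences are dropped
  w <- wilcoxonSignedRank(c(1, 2, 5, 7), c(1, 2, 4, 5))
  expect_identical(w$nUsed, 2L)
})

test_that("normal approximation tracks the exact enumeration oracle", {
  set.seed(67)
  for (rep in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8)
    pN <- wilcoxonSignedRank(a, b)$p.value
    # independent enumeration over all 2^8 sign assignments
    d <- a - b; d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(grid %*% r)
    pE <- mean(abs(Wall - n * (n + 1) / 4) >= abs(W - n * (n + 1) / 4) - 1e-12)
    expect_equal(wilcoxonSignedRank(a, b, mode = "exact")$p.value, pE,
                 tolerance = 1e-12)
    # the approximation stays within its usual error band at n = 8 (the
    # discrete exact distribution has steps of ~2/2^8 near the center)
    expect_lt(abs(pN - pE), 0.1)
  }
})

test_that("group t-test separates groups and respects location invariance", {
  # identical value distributions in both groups are indistinguishable
  expect_equal(groupTTest(c(1, 2, 1, 2), c(0, 0, 1, 1)), 1)
  set.seed(71)
  pred <- c(rnorm(4, 0, 0.001), rnorm(4, 10, 0.001))
  lab <- rep(c(0, 1), each = 4)
  expect_lt(groupTTest(pred, lab), 1e-6)
  expect_equal(groupTTest(pred + 100, lab), groupTTest(pred, lab))
  # pooled-variance variant agrees with stats::t.test
  expect_equal(groupTTest(pred, lab, varEqual = TRUE),
               stats::t.test(pred[lab == 1], pred[lab == 0],
                             var.equal = TRUE)$p.value)
  expect_error(groupTTest(pred, c(0, rep(1, 7))), "2 members")
})

test_that("benchmark harness produces the full runs-by-combinations structure", {
  ds <- syntheticDataset(p = 30, q = 14, n = 8, nInformative = 3,
                         noiseSd = 0.5, seed = 31)
  rep <- runBenchmark(ds$D, ds$y, ds$T, ds$labels,
                      algorithms = c("B", "A1", "A2"),
                      learners = list(learnerSpec("svr-linear"),
                                      learnerSpec("svr-sigmoid"),
                                      learnerSpec("rr")),
                      sizes = c(30, 28, 27, 26, 25), seed = 2,
                      topKGenes = 12, kDoubleprime = 2)
  pr <- perRunAUC(rep)
  expect_identical(nrow(pr), 9L * 5L)          # 9 combinations x 5 runs
  expect_identical(length(maucValues(rep)), 9L)
  expect_true(all(pr$auc >= 0 & pr$auc <= 1))
  for (cb in names(maucValues(rep))) {
    sel <- paste0(pr$algorithm, "+", pr$learner) == cb
    expect_equal(unname(maucValues(rep)[cb]), mean(pr$auc[sel]))
  }
  W <- pairwiseWilcoxon(rep)
  expect_identical(dim(W), c(9L, 9L))
  expect_true(all(is.na(diag(W))))
  offdiag <- W[upper.tri(W)]
  expect_true(all(offdiag >= 0 & offdiag <= 1, na.rm = TRUE))

  f <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_named(parsed, c("per_run", "mauc", "pairwise_wilcoxon",
                         "group_ttest_p"))
})
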