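# Helper: a paired set straight from matrices, bypassing interpolation, so
# geometric cases can be constructed by hand (columns must still be 2n).
pairedFromMatrix <- function(feats, responses = numeric(0)) {
  new("PairedSet", features = feats, responses = responses,
      lambda = 0.3, kPrime = 1L)
}

test_that("weights are minimum Euclidean distances to the test rows", {
  tr <- mat(c(0, 0, 3, 4), nrow = 2)
  te <- mat(c(0, 1), nrow = 1, prefix = "T")
  w <- computeWeights(tr, te)
  expect_equal(unname(w), c(1, 3 * sqrt(2)), tolerance = 1e-12)

  # training row identical to a test row gets weight zero
  te2 <- rbind(te, tr[2, , drop = FALSE])
  rownames(te2) <- c("T01", "T02")
  w2 <- computeWeights(tr, te2)
  expect_equal(unname(w2[2]), 0)

  # appending test rows never increases a weight
  expect_true(all(w2 <= w + 1e-12))

  set.seed(21)
  A <- mat(rnorm(10 * 4), nrow = 10)
  B <- mat(rnorm(6 * 4), nrow = 6, prefix = "T")
  expect_equal(unname(computeWeights(A, B)),
               apply(bruteDist(A, B), 1, min), tolerance = 1e-10)

  expect_error(computeWeights(A, B[0, , drop = FALSE]), "empty")
})

test_that("median partition splits at the median with overlap only on ties", {
  set.seed(3)
  G4 <- pairedFromMatrix(mat(rnorm(4 * 4), nrow = 4), responses = rnorm(4))
  w4 <- c(1, 2, 3, 4)
  p4 <- medianPartition(G4, w4)
  expect_identical(p4@xIdx, 1:2)
  expect_identical(p4@zIdx, 3:4)
  expect_equal(partitionMedian(p4), 2.5)

  G5 <- pairedFromMatrix(mat(rnorm(5 * 4), nrow = 5), responses = rnorm(5))
  p5 <- medianPartition(G5, c(5, 1, 3, 2, 4))
  expect_identical(sort(p5@xIdx), c(2L, 3L, 4L))
  expect_identical(sort(p5@zIdx), c(1L, 3L, 5L))
  expect_identical(intersect(p5@xIdx, p5@zIdx), 3L)

  # total tie: both halves are everything
  pt <- medianPartition(G4, rep(2, 4))
  expect_identical(pt@xIdx, 1:4)
  expect_identical(pt@zIdx, 1:4)
})

test_that("seed assignment picks the larger-error side as S, ties toward X", {
  # X rows follow y = 2 * x1 exactly. Z consists of duplicated feature rows
  # whose responses are 2 * x1 +/- 2, so the least-squares fit on Z is the
  # true line: the Z-trained model is exact on X (MSE 0) while the X-trained
  # model scores MSE 4 against Z's perturbed responses.
  set.seed(17)
  xfeat <- mat(rnorm(6 * 2), nrow = 6)
  zbase <- mat(rnorm(3 * 2), nrow = 3)
  zfeat <- zbase[rep(1:3, each = 2), ]
  feats <- rbind(xfeat, zfeat)
  rownames(feats) <- sprintf("S%02d", 1:12)
  lin <- 2 * feats[, 1]
  resp <- c(lin[1:6], lin[7:12] + rep(c(2, -2), 3))
  w <- c(rep(0, 6), rep(10, 6))  # X = rows 1:6 (near), Z = rows 7:12 (far)
  G <- pairedFromMatrix(feats, resp)
  part <- medianPartition(G, w)
  seed <- assignSeedSet(part, learnerSpec("rr", alpha = 1e-8))
  expect_equal(seed@perSideMSE, c(4, 0), tolerance = 1e-4)
  expect_identical(seed@jStar, 1L)         # X-trained side erred more: S = X
  expect_identical(sort(seed@sIdx), 1:6)

  # swapping which half is near flips the argmax to the Z-trained side:
  # X becomes the perturbed rows (its model is exact on the linear Z), Z the
  # linear rows (its model scores MSE 4 against X's perturbed responses)
  partSwap <- medianPartition(G, rev(w))
  seedSwap <- assignSeedSet(partSwap, learnerSpec("rr", alpha = 1e-8))
  expect_equal(seedSwap@perSideMSE, c(0, 4), tolerance = 1e-4)
  expect_identical(seedSwap@jStar, 2L)     # S = Z = the linear rows
  expect_identical(sort(seedSwap@sIdx), 1:6)

  # symmetric halves give an exact tie, resolved toward S = X
  featsSym <- rbind(xfeat, xfeat)
  rownames(featsSym) <- sprintf("S%02d", 1:12)
  Gsym <- pairedFromMatrix(featsSym, c(lin[1:6], lin[1:6]))
  psym <- medianPartition(Gsym, rep(c(0, 10), each = 6))
  ssym <- assignSeedSet(psym)
  expect_identical(ssym@jStar, 1L)
  expect_equal(ssym@perSideMSE[1], ssym@perSideMSE[2])

  # inverted rule flips the roles
  sinv <- assignSeedSet(part, learnerSpec("rr", alpha = 1e-8),
                        rule = "inverted")
  expect_identical(sort(sinv@sIdx), 7:12)

  # all-constant features on one side is a named degenerate error
  featsC <- feats; featsC[1:6, ] <- 1
  Gc <- pairedFromMatrix(featsC, resp)
  expect_error(assignSeedSet(medianPartition(Gc, w)), "side X")
})

test_that("seed pool size follows the order-statistic count for p = 4..9", {
  set.seed(31)
  for (p in 4:9) {
    feats <- mat(rnorm(p * 6), nrow = p)
    G <- pairedFromMatrix(feats, rnorm(p))
    w <- sample(seq_len(p))  # distinct weights
    seed <- assignSeedSet(medianPartition(G, w))
    expected <- if (p %% 2 == 0) p / 2 else (p + 1) / 2
    expect_identical(length(seed@sIdx), as.integer(expected))
  }
})

test_that("disagreement scores equal the weighted prediction variance", {
  expect_equal(disagreementScores(matrix(c(0, 2), 2, 1), c(0.5, 0.5)), 1)
  expect_equal(disagreementScores(matrix(c(1, 1, 4), 3, 1), rep(1 / 3, 3)), 2)
  expect_equal(disagreementScores(matrix(5, 3, 4), rep(1 / 3, 3)),
               rep(0, 4))

  set.seed(13)
  P <- matrix(rnorm(3 * 7), 3, 7)
  wp <- c(0.2, 0.3, 0.5)
  oracle <- sapply(seq_len(7), function(j) {
    f <- sum(wp * P[, j])
    sum(wp * (P[, j] - f)^2)
  })
  expect_equal(disagreementScores(P, wp), oracle, tolerance = 1e-9)

  expect_error(disagreementScores(P, c(0.2, 0.3, 0.4)), "sum to 1")
})

test_that("QBC transfers exactly k'' rows from U to S, ties toward low index", {
  set.seed(41)
  ds <- syntheticDataset(p = 14, q = 6, n = 5, nInformative = 3,
                         noiseSd = 0.3, seed = 8)
  G <- buildPairedTraining(ds$D, ds$y)
  Gp <- buildPairedTest(ds$T)
  w <- computeWeights(G, Gp)
  seed <- assignSeedSet(medianPartition(G, w))
  s0 <- length(seed@sIdx); u0 <- length(seed@uIdx)

  expect_identical(nrow(qbcSelect(seed, kDoubleprime = 0)), s0)
  for (k in c(1, 3)) {
    S <- qbcSelect(seed, kDoubleprime = k)
    expect_identical(nrow(S), s0 + as.integer(k))
    # conservation: selected rows are original rows, no duplicates
    expect_true(all(sampleIds(S) %in% sampleIds(G)))
    expect_false(anyDuplicated(sampleIds(S)) > 0)
    # responses travel with their rows
    expect_equal(pairedResponses(S),
                 unname(ds$y[sampleIds(S)]))
  }
  expect_error(qbcSelect(seed, kDoubleprime = u0 + 1), "exceeds")
})

test_that("selection is invariant to row permutation of U up to tie-breaking", {
  ds <- syntheticDataset(p = 12, q = 5, n = 4, nInformative = 2,
                         noiseSd = 0.2, seed = 19)
  G <- buildPairedTraining(ds$D, ds$y)
  Gp <- buildPairedTest(ds$T)
  S1 <- linkFilter(G, Gp, kDoubleprime = 3)
  # permute training rows; the same cell lines must be selected
  perm <- c(4, 1, 12, 7, 2, 9, 5, 11, 3, 10, 8, 6)
  Gperm <- G[perm]
  S2 <- linkFilter(Gperm, Gp, kDoubleprime = 3)
  expect_setequal(sampleIds(S1), sampleIds(S2))
})

test_that("filtered set size is floor(p/2) + k'' under distinct weights", {
  for (p in c(20, 21)) {
    ds <- syntheticDataset(p = p, q = 8, n = 6, nInformative = 3, seed = p)
    G <- buildPairedTraining(ds$D, ds$y)
    Gp <- buildPairedTest(ds$T)
    w <- computeWeights(G, Gp)
    expect_false(anyDuplicated(w) > 0)
    S <- linkFilter(G, Gp, kDoubleprime = 5)
    expected <- if (p %% 2 == 0) p / 2 else (p + 1) / 2
    expect_identical(nrow(S), as.integer(expected + 5))
  }
})
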