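test_that("binning follows the floor convention without clipping", {
  rec <- makeRecord(a = c(-0.3, 0.0, 0.49, 0.5))
  b <- binRecord(rec)
  expect_identical(as.integer(binIndices(b)), c(-1L, 0L, 0L, 1L))

  const <- binRecord(makeRecord(a = rep(0.2, 10)))
  expect_identical(unique(as.integer(binIndices(const))), 0L)

  # halving the width doubles the resolution on a ramp: verify bin counts
  # against a direct enumeration
  ramp <- seq(0, 1.999, by = 0.001)
  for (w in c(0.5, 0.25)) {
    b <- binRecord(makeRecord(a = ramp), BinningConfig(binWidth = w))
    expect_identical(as.integer(binIndices(b)), as.integer(floor(ramp / w)))
    expect_equal(length(unique(binIndices(b))), 2 / w)
  }

  bad <- makeRecord(a = c(0.1, NaN, 0.3))
  expect_error(binRecord(bad), "sample 2", class = "ecgrContractError")
})

test_that("entropy matches direct evaluation of the plug-in formula", {
  expect_equal(channelEntropy(makeRecord(a = rep(1.1, 50)), "a"), 0)
  expect_equal(channelEntropy(makeRecord(a = c(0.1, 0.6, 0.1, 0.6)), "a"), 1)
  # bin counts {4,2,1,1}: H = 1.75 bits
  rec <- makeRecord(a = c(rep(0.1, 4), rep(0.6, 2), 1.1, 1.6))
  expect_equal(channelEntropy(rec, "a"), 1.75)
})

test_that("joint entropy reduces, collapses for copies, and adds for independents", {
  b <- oracleBinned()
  expect_equal(jointEntropy(b, subset = "a"), channelEntropy(b, "a"))

  dup <- binRecord(makeRecord(a = c(0.1, 0.6, 1.2, 0.1), b = c(0.1, 0.6, 1.2, 0.1)))
  expect_equal(jointEntropy(dup), channelEntropy(dup, "a"))

  ind <- binRecord(makeRecord(a = c(0.1, 0.1, 0.6, 0.6), b = c(0.1, 0.6, 0.1, 0.6)))
  expect_equal(jointEntropy(ind), 2)
  expect_equal(mutualInformation(ind, "a", "b"), 0)

  expect_error(jointEntropy(b, subset = character(0)), class = "ecgrContractError")
  expect_error(jointEntropy(b, subset = c(1, 1)), class = "ecgrContractError")
  # permutation invariance within the subset
  expect_equal(jointEntropy(b, subset = c(1, 3, 2)), jointEntropy(b, subset = c(3, 2, 1)))
})

test_that("mutual information and NMI behave for copies, relabelings and errors", {
  rec <- randomRecord(500, 1, seed = 7)
  two <- MultichannelRecord(cbind(signalData(rec), signalData(rec)),
                            channelNames = c("x", "copy"))
  b <- binRecord(two)
  expect_equal(mutualInformation(b, "x", "copy"), channelEntropy(b, "x"))
  expect_equal(nmi(b, "x", "copy"), 1)
  expect_equal(mutualInformation(b, "x", "x"), channelEntropy(b, "x"))

  # shifting by an integer number of bins relabels bins bijectively
  shifted <- MultichannelRecord(cbind(signalData(rec), signalData(rec) + 1.5),
                                channelNames = c("x", "shift"))
  bs <- binRecord(shifted)
  expect_equal(mutualInformation(bs, "x", "shift"), channelEntropy(bs, "x"))

  expect_error(nmi(b, "x", "nope"), class = "ecgrContractError")
  const2 <- binRecord(makeRecord(a = rep(0.1, 5), b = rep(0.2, 5)))
  expect_error(nmi(const2, "a", "b"), class = "ecgrUndefinedError")
})

test_that("NMI matrix is symmetric with unit diagonal and matches pairwise calls", {
  rec <- randomRecord(400, 4, seed = 12)
  b <- binRecord(rec)
  m <- nmiMatrix(b)
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m, t(m))
  for (i in 1:4) for (j in 1:4)
    expect_equal(m[i, j], nmi(b, i, j))
})

test_that("redundancy hits analytic anchors: duplicates, independents, singles", {
  x <- rnorm(3000)
  dup <- binRecord(MultichannelRecord(cbind(a = x, b = x, c = rnorm(3000))))
  expect_equal(channelRedundancy(dup, "a"), 1)
  expect_equal(setRedundancy(binRecord(MultichannelRecord(cbind(a = x, b = x)))), 1)

  ind <- binRecord(randomRecord(1e5, 2, seed = 99))
  expect_lt(channelRedundancy(ind, 1), 0.02)

  expect_equal(setRedundancy(binRecord(MultichannelRecord(cbind(a = x)))), 0)
  expect_equal(setRedundancy(binRecord(randomRecord(100, 3, seed = 1)),
                             subset = "ch2"), 0)

  expect_error(channelRedundancy(binRecord(MultichannelRecord(cbind(a = x)))),
               class = "ecgrContractError")
  withConst <- binRecord(makeRecord(a = rnorm(50), b = rep(0.1, 50)))
  expect_error(channelRedundancy(withConst, "b"), class = "ecgrUndefinedError")
  allConst <- binRecord(makeRecord(a = rep(0.1, 5), b = rep(0.2, 5)))
  expect_error(setRedundancy(allConst), class = "ecgrUndefinedError")
})

test_that("entropy family agrees with the explicit joint-distribution oracle", {
  b <- oracleBinned()
  bins <- binIndices(b)
  n <- ncol(bins)
  for (size in 1:n) {
    for (cols in as.data.frame(combn(n, size))) {
      expect_equal(jointEntropy(b, subset = cols), bruteEntropy(bins, cols))
    }
  }
  for (i in seq_len(n)) {
    expect_equal(channelRedundancy(b, i), bruteChannelRedundancy(bins, i))
  }
  for (size in 2:n) {
    for (cols in as.data.frame(combn(n, size))) {
      expect_equal(setRedundancy(b, subset = cols),
                   bruteSetRedundancy(bins, cols))
    }
  }
})

test_that("information quantities respect bounds and log-base invariance", {
  for (seed in 1:5) {
    rec <- randomRecord(300, 3, seed = seed)
    b <- binRecord(rec)
    for (i in 1:3) for (j in 1:3) {
      mi <- mutualInformation(b, i, j)
      expect_gte(mi, 0)
      expect_lte(mi, min(channelEntropy(b, i), channelEntropy(b, j)) + 1e-12)
    }
    bNat <- binRecord(rec, BinningConfig(logBase = exp(1)))
    expect_equal(nmi(b, 1, 2), nmi(bNat, 1, 2), tolerance = 1e-9)
    expect_equal(setRedundancy(b), setRedundancy(bNat), tolerance = 1e-9)
    expect_equal(channelRedundancy(b, 2), channelRedundancy(bNat, 2),
                 tolerance = 1e-9)
  }
})

test_that("finite-sample redundancy bias shrinks with sample count", {
  rs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(421)
    setRedundancy(binRecord(MultichannelRecord(
      matrix(runif(3 * n, 0, 2), ncol = 3))))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[3], 0.02)
})

test_that("Pearson morphology correlation hits its anchors", {
  x <- sin(seq(0, 8 * pi, length.out = 1001)[-1001])
  rec <- makeRecord(s = x, negs = -x,
                    c = cos(seq(0, 8 * pi, length.out = 1001)[-1001]))
  expect_equal(pcc(rec, "s", "s"), 1)
  expect_equal(pcc(rec, "s", "negs"), -1)
  expect_equal(pcc(rec, "s", "c"), 0, tolerance = 1e-6)
  flat <- makeRecord(a = rnorm(10), b = rep(1, 10))
  expect_error(pcc(flat, "a", "b"), class = "ecgrUndefinedError")
})
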