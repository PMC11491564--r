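test_that("absolute angles fold into [0,90] and respect planes", {
  expect_equal(absoluteAngle("I", "aVF"), 90)
  expect_equal(absoluteAngle("II", "II"), 0)
  expect_equal(absoluteAngle("II", "aVF"), 30)
  expect_equal(absoluteAngle("III", "aVR"), 90)
  expect_equal(absoluteAngle("V1", "V6"), 65)
  expect_error(absoluteAngle("I", "V1"), "plane", class = "ecgrContractError")
  expect_error(absoluteAngle("I", "W9"), class = "ecgrContractError")
})

test_that("the geometry table covers each standard lead once", {
  g <- leadGeometry()
  expect_setequal(g$lead, c("I", "II", "III", "aVR", "aVL", "aVF",
                            paste0("V", 1:6)))
  expect_false(anyDuplicated(g$lead) > 0)
  expect_identical(g$plane[g$lead %in% c("I", "II", "III", "aVR", "aVL", "aVF")],
                   rep("frontal", 6))
  expect_identical(g$plane[grepl("^V", g$lead)], rep("transverse", 6))
})

test_that("fixed subsets are the shipped constants", {
  expect_identical(fixedSubset("eight"),
                   c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  expect_identical(fixedSubset("six"), c("II", "aVL", "V1", "V3", "V5", "V6"))
  expect_identical(fixedSubset("three"), c("aVR", "III", "V2"))
  expect_identical(fixedSubset("one"), "V6")
  expect_error(fixedSubset("two"), class = "ecgrContractError")
})

test_that("pair ranking orders by set redundancy with the duplicate pair last", {
  x <- rnorm(2000); y <- rnorm(2000)
  rec <- MultichannelRecord(cbind(a = x, b = x, c = y))
  ranked <- rankOrthogonalPairs(rec, list(c("a", "b"), c("a", "c")))
  expect_identical(ranked$leads, c("a-c", "a-b"))
  expect_equal(ranked$setR[2], 1)

  single <- rankOrthogonalPairs(rec, list(c("a", "c")))
  expect_equal(nrow(single), 1)

  # scores equal the two-channel redundancy evaluated pair by pair
  b <- binRecord(rec)
  expect_equal(ranked$setR[1], setRedundancy(b, subset = c("a", "c")))
})

test_that("the most representative lead maximizes channel redundancy", {
  x <- rnorm(2000)
  rec <- MultichannelRecord(cbind(a = x, b = x + rnorm(2000, sd = 0.05),
                                  ind = rnorm(2000), c = x))
  expect_identical(mostRepresentativeLead(rec), "a")

  b <- binRecord(rec)
  sweep <- channelRedundancy(b)
  expect_identical(mostRepresentativeLead(b),
                   channelNames(b)[which.max(sweep)])
  expect_identical(names(which.min(sweep)), "ind")

  withConst <- MultichannelRecord(cbind(a = x, flat = rep(0.1, 2000)))
  expect_error(mostRepresentativeLead(withConst), "flat",
               class = "ecgrUndefinedError")
})

test_that("subset search matches a full scan and greedy never beats it", {
  rec <- randomRecord(800, 5, seed = 17)
  d <- signalData(rec)
  d[, 2] <- d[, 1] + rnorm(800, sd = 0.1)     # a correlated pair to avoid
  rec <- MultichannelRecord(d, channelNames = channelNames(rec))
  b <- binRecord(rec)

  res <- searchMinRedundancySubset(b, 3, "exhaustive")
  combos <- combn(5, 3)
  scores <- apply(combos, 2, function(ix) setRedundancy(b, subset = ix))
  expect_equal(res$setR, min(scores))
  expect_identical(res$leads, channelNames(b)[combos[, which.min(scores)]])

  g <- searchMinRedundancySubset(b, 3, "greedy")
  expect_gte(g$setR, res$setR - 1e-12)
  expect_identical(g$mode, "greedy")

  full <- searchMinRedundancySubset(b, 5, "exhaustive")
  expect_setequal(full$leads, channelNames(b))

  dup <- MultichannelRecord(cbind(a = d[, 1], b = d[, 1], c = d[, 3]))
  r2 <- searchMinRedundancySubset(binRecord(dup), 2, "exhaustive")
  expect_false(setequal(r2$leads, c("a", "b")))

  expect_error(searchMinRedundancySubset(b, 0), class = "ecgrContractError")
  expect_error(searchMinRedundancySubset(b, 6), class = "ecgrContractError")
})

test_that("orthogonal frontal pairs score lower redundancy on dipole data", {
  corp <- sharedCorpus()
  b <- binRecord(concatenateRecords(corp))
  frontal <- c("I", "II", "III", "aVR", "aVL", "aVF")
  pairs <- combn(frontal, 2, simplify = FALSE)
  angles <- vapply(pairs, function(p) absoluteAngle(p[1], p[2]), numeric(1))
  scores <- vapply(pairs, function(p) setRedundancy(b, subset = p), numeric(1))
  expect_lt(cor(angles, scores, method = "spearman"), 0)
})
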