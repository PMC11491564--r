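test_that("limb-lead derivation satisfies the Einthoven and Goldberger identities", {
  zero <- makeRecord(I = rep(0, 10), II = rep(0, 10))
  expect_true(all(signalData(deriveLimbLeads(zero)) == 0))

  rec <- makeRecord(I = rnorm(200), II = rnorm(200))
  d <- signalData(deriveLimbLeads(rec))
  expect_equal(d[, "I"] + d[, "III"] - d[, "II"], rep(0, 200))
  expect_equal(d[, "aVR"] + d[, "aVL"] + d[, "aVF"], rep(0, 200))
  expect_equal(d[, "aVR"], -(d[, "I"] + d[, "II"]) / 2)

  expect_error(deriveLimbLeads(makeRecord(I = rnorm(10), V1 = rnorm(10))),
               "II", class = "ecgrContractError")
})

test_that("inverse Dower is the exact pseudoinverse of the forward projection", {
  zero <- MultichannelRecord(matrix(0, 10, 3), channelNames = c("X", "Y", "Z"))
  expect_true(all(signalData(dowerForward(zero)) == 0))
  expect_true(all(signalData(inverseDower(augment15(
    MultichannelRecord(matrix(0, 10, 12),
                       channelNames = leadGeometry()$lead)))) == 0))

  v <- MultichannelRecord(matrix(rnorm(300), 100, 3),
                          channelNames = c("X", "Y", "Z"))
  leads <- dowerForward(v)
  back <- inverseDower(leads)
  expect_identical(channelNames(back), c("X", "Y", "Z"))
  expect_equal(signalData(back), signalData(v), tolerance = 1e-9)

  # linearity and rank of the forward map
  v2 <- MultichannelRecord(3 * signalData(v), channelNames = c("X", "Y", "Z"))
  expect_equal(signalData(dowerForward(v2)), 3 * signalData(leads))
  expect_equal(qr(dowerForwardSpec()@matrix)$rank, 3)

  # a unit impulse on lead I reads off the I-column of the IDT matrix
  spec <- inverseDowerSpec()
  imp <- MultichannelRecord(
    matrix(0, 2, 8, dimnames = list(NULL, spec@inputChannels)))
  d <- signalData(imp); d[1, "I"] <- 1
  imp <- MultichannelRecord(d)
  out <- signalData(applyTransform(spec, imp))
  expect_equal(out[1, ], spec@matrix[, match("I", spec@inputChannels)],
               ignore_attr = TRUE)

  expect_error(inverseDower(makeRecord(I = rnorm(10), II = rnorm(10))),
               "V1", class = "ecgrContractError")
  expect_error(dowerForward(makeRecord(X = rnorm(10))),
               class = "ecgrContractError")
})

test_that("15-channel augmentation appends the estimated vectorcardiogram", {
  rec <- sharedCorpus()[[1]]
  aug <- augment15(rec)
  expect_equal(nChannels(aug), 15)
  expect_identical(channelNames(aug)[1:12], channelNames(rec))
  expect_identical(channelNames(aug)[13:15], c("X", "Y", "Z"))
  expect_equal(signalData(aug)[, 1:12], signalData(rec))
  expect_equal(signalData(aug)[, 13:15], signalData(inverseDower(rec)))
})

test_that("corpus PCA produces an orthonormal, variance-ordered model", {
  corp <- sharedCorpus()
  model <- pcaFit(corp)
  rot <- pcaRotation(model)
  expect_equal(rot %*% t(rot), diag(12), tolerance = 1e-8)
  vf <- explainedVariance(model)
  expect_true(all(diff(vf) <= 1e-12))
  expect_equal(sum(vf), 1)
  # sign convention: dominant entry of each component is positive
  expect_true(all(apply(rot, 1, function(r) r[which.max(abs(r))] > 0)))

  # full reconstruction of the centered corpus
  corpus <- concatenateRecords(corp)
  centered <- sweep(signalData(corpus), 2, pcaCenter(model))
  scores <- signalData(pcaTransform(corpus, model, 12))
  expect_equal(scores %*% rot, centered, tolerance = 1e-8,
               ignore_attr = TRUE)

  # per-component score variances match the eigenvalue ordering
  varScores <- apply(scores, 2, var)
  expect_equal(varScores / sum(varScores), vf, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(cor(scores)[upper.tri(diag(12))])), 1e-8)

  one <- pcaTransform(corpus, model, 1)
  expect_identical(channelNames(one), "PC1")
  expect_equal(signalData(one)[, 1], scores[, 1])

  expect_error(pcaTransform(corpus, model, 0), class = "ecgrContractError")
  expect_error(pcaTransform(corpus, model, 13), class = "ecgrContractError")
  flat <- MultichannelRecord(matrix(0.5, 100, 3))
  expect_error(pcaFit(RecordCollection(list(flat))), class = "ecgrUndefinedError")
})

test_that("PCA separates dipolar rank from isotropic noise", {
  # noise-free dipole corpus is rank 3: the leading 3 fractions sum to 1
  clean <- simulateCorpus(4, c(NORM = 1),
                          dipoleParams(seed = 5L, noiseSdMv = 0,
                                       electrodeJitterDeg = 0))
  vf <- explainedVariance(pcaFit(clean))
  expect_equal(sum(vf[1:3]), 1, tolerance = 1e-9)
  expect_true(all(vf[4:12] < 1e-9))

  # with noise present, components beyond 3 are non-negligible
  noisy <- simulateCorpus(4, c(NORM = 1),
                          dipoleParams(seed = 5L, noiseSdMv = 0.05))
  vfN <- explainedVariance(pcaFit(noisy))
  expect_true(all(vfN[4:12] > 1e-9))

  # isotropic white noise spreads variance evenly
  white <- MultichannelRecord(matrix(rnorm(12 * 4000), ncol = 12))
  vfW <- explainedVariance(pcaFit(RecordCollection(list(white))))
  expect_lt(max(abs(vfW - 1 / 12)), 0.015)
})
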