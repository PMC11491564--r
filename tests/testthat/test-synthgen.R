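test_that("the dipole generator is deterministic and honors degenerate params", {
  p <- dipoleParams(seed = 9L)
  expect_equal(signalData(simulateVcg(p)), signalData(simulateVcg(p)))
  expect_equal(signalData(simulate12Lead(p)), signalData(simulate12Lead(p)))

  silent <- lapply(c("x", "y", "z"), function(a)
    data.frame(center = 0, width = 0.1, amplitude = 0))
  names(silent) <- c("x", "y", "z")
  pz <- dipoleParams(waveComponents = silent, restOffsetMv = c(0, 0, 0),
                     noiseSdMv = 0, electrodeJitterDeg = 0, seed = 1L)
  expect_true(all(signalData(simulate12Lead(pz)) == 0))

  expect_error(dipoleParams(rateHz = 500, durationS = 0.0011),
               class = "ecgrContractError")
  expect_error(dipoleParams(noiseSdMv = -1), class = "ecgrContractError")
  badWaves <- defaultWaveComponents()
  badWaves$x$width[1] <- 0
  expect_error(dipoleParams(waveComponents = badWaves),
               class = "ecgrContractError")
})

test_that("a lone QRS bump reproduces its configured amplitude on its axis", {
  wc <- list(x = data.frame(center = 0, width = 0.09, amplitude = 1.1),
             y = data.frame(center = 0, width = 0.09, amplitude = 0),
             z = data.frame(center = 0, width = 0.09, amplitude = 0))
  p <- dipoleParams(durationS = 2, heartRateBpm = 60, rrJitterFrac = 0,
                    waveComponents = wc, beatRotSd = 0, beatScaleSd = 0,
                    restOffsetMv = c(0, 0, 0), noiseSdMv = 0,
                    electrodeJitterDeg = 0, seed = 3L)
  v <- signalData(simulateVcg(p))
  expect_true(all(v[, c("Y", "Z")] == 0))
  expect_equal(max(v[, "X"]), 1.1, tolerance = 0.01)
})

test_that("noise- and jitter-free 12-lead projections are a rank-3 dipole system", {
  p <- dipoleParams(noiseSdMv = 0, electrodeJitterDeg = 0, seed = 21L)
  d <- signalData(simulate12Lead(p))
  expect_equal(d[, "I"] + d[, "III"] - d[, "II"], rep(0, nrow(d)),
               tolerance = 1e-9)
  expect_equal(d[, "aVR"] + d[, "aVL"] + d[, "aVF"], rep(0, nrow(d)),
               tolerance = 1e-9)
  sv <- svd(cov(d))$d
  expect_lt(sv[4] / sv[1], 1e-12)
})

test_that("dipole projections at fixed angles match the plane geometry", {
  p <- dipoleParams(seed = 4L)
  vcg <- simulateVcg(p)
  pr <- projectDipole(vcg, angles = c(0, 90), plane = "frontal",
                      names = c("along_x", "along_y"))
  expect_equal(signalData(pr)[, "along_x"],
               signalData(vcg)[, "X"], ignore_attr = TRUE)
  expect_equal(signalData(pr)[, "along_y"],
               signalData(vcg)[, "Y"], ignore_attr = TRUE)
  tr <- projectDipole(vcg, angles = 90, plane = "transverse")
  expect_equal(signalData(tr)[, 1], signalData(vcg)[, "Z"],
               ignore_attr = TRUE)
})

test_that("corpus simulation reproduces the requested class mixture", {
  allNorm <- simulateCorpus(5, c(NORM = 1),
                            dipoleParams(seed = 11L, durationS = 1))
  expect_true(all(vapply(records(allNorm), recordLabel, character(1)) == "NORM"))

  expect_error(simulateCorpus(0), class = "ecgrContractError")
  expect_error(simulateCorpus(3, c(NORM = 0.5, MI = 0.4)),
               class = "ecgrContractError")
  expect_error(simulateCorpus(3, c(GOOD = 1)), class = "ecgrContractError")

  mix <- c(NORM = 0.5, MI = 0.3, HYP = 0.2)
  corp <- simulateCorpus(1000, mix, dipoleParams(seed = 77L, durationS = 0.1))
  labs <- vapply(records(corp), recordLabel, character(1))
  freq <- table(labs)[names(mix)] / 1000
  expect_true(all(abs(freq - mix) < 3 * sqrt(mix * (1 - mix) / 1000) + 1e-9))

  # reproducibility from the base seed
  corp2 <- simulateCorpus(5, mix, dipoleParams(seed = 77L, durationS = 0.1))
  corp3 <- simulateCorpus(5, mix, dipoleParams(seed = 77L, durationS = 0.1))
  expect_equal(lapply(records(corp2), signalData),
               lapply(records(corp3), signalData))
})

test_that("class perturbations change morphology without breaking the dipole model", {
  base <- dipoleParams(seed = 31L, durationS = 2, noiseSdMv = 0,
                       electrodeJitterDeg = 0)
  corp <- simulateCorpus(5, c(MI = 1), base, subjectRotSd = 0,
                         subjectScaleSd = 0)
  norm <- simulateCorpus(5, c(NORM = 1), base, subjectRotSd = 0,
                         subjectScaleSd = 0)
  # MI perturbation scales amplitudes down and rotates the axis
  expect_false(isTRUE(all.equal(signalData(corp[[1]]), signalData(norm[[1]]))))
  sv <- svd(cov(signalData(corp[[1]])))$d
  expect_lt(sv[4] / sv[1], 1e-12)
})
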