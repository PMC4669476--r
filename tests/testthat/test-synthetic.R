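test_that("pair enumeration gives 45 undirected and 90 directed pairs", {
  pu <- enumeratePairs(10)
  pd <- enumeratePairs(10, directed = TRUE)
  expect_equal(nrow(pu), 45)
  expect_equal(nrow(pd), 90)
  expect_true(all(pu[, "from"] < pu[, "to"]))
  expect_true(all(pd[, "from"] != pd[, "to"]))
  # row-major order over i < j
  expect_equal(pu[1:3, "to"], c(2, 3, 4))
  expect_equal(anyDuplicated(paste(pd[, 1], pd[, 2])), 0L)
})

test_that("spec constructors validate their invariants", {
  expect_error(driveSpec(1, 4, 1, 0.5), "centerFreq")
  expect_error(driveSpec(10, -1, 1, 0.5), "bandwidth")
  expect_error(driveSpec(10, 4, 1, -0.1), "gain")
  expect_error(driveSpec(10, 4, integer(), 0.5), "targets")
  expect_error(varCouplingSpec(list(diag(1.1, 2)), diag(2)), "unstable")
  expect_error(varCouplingSpec(list(diag(0.5, 2)),
                               matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(studyDesign(trialDuration = 0.3, fs = 11,
                           channelLabels = "a"), "integer sample count")
})

test_that("carrier generation is deterministic and band-limited", {
  des <- smallDesign(trialDuration = 10, nChannels = 2)
  x1 <- generateCarrier(2, des, seed = 1)
  x2 <- generateCarrier(2, des, seed = 1)
  expect_identical(x1, x2)
  x3 <- generateCarrier(2, des, seed = 2)
  expect_false(identical(x1, x3))
  expect_error(generateCarrier(2, des, band = c(5, 1500)), "band")
  # >= 99% of Welch power inside the 5-400 Hz band
  sp <- normalizedPsd(x1, fs = 2000)
  inBand <- sp$freqs >= 5 & sp$freqs <= 400
  expect_gt(min(rowSums(sp$psd[, inBand])), 0.99)
  expect_lt(max(abs(rowMeans(x1))), 0.05)
})

test_that("independent carriers show only chance-level coherence", {
  des <- smallDesign(trialDuration = 10, nChannels = 2)
  x <- generateCarrier(2, des, seed = 5)
  thr <- surrogateThreshold(list(x), fs = 2000, nSurrogates = 60, seed = 6)
  coh <- poolCoherence(list(welchCoherency(x, fs = 2000)))
  exceed <- mean(connectivityValues(coh) > thr$thresholds)
  expect_lt(exceed, 0.10)
})

test_that("common-drive studies plant band-specific envelope coherence", {
  des <- smallDesign(trialDuration = 30, nChannels = 4)
  st <- generateCommonDriveStudy(des, list(driveSpec(10, 4, c(1, 2), 0.5)),
                                 seed = 3)
  env <- highpassRectify(st)
  pool <- poolCoherence(lapply(env@trials, welchCoherency, fs = 2000))
  f <- frequencies(pool)
  v <- connectivityValues(pool)
  band <- f >= 1 & f <= 30
  peakF <- f[band][which.max(v[1, band])]
  expect_lte(abs(peakF - 10), 2)
  thr <- surrogateThreshold(env@trials, fs = 2000, nSurrogates = 60,
                            seed = 4)
  expect_gt(v[1, f == 10], thr$thresholds[1, f == 10])
  # pair (3,4) shares no drive: chance-level exceedance
  nullRow <- which(pairIndex(pool)[, "from"] == 3 &
                     pairIndex(pool)[, "to"] == 4)
  nullExc <- mean(v[nullRow, band] > thr$thresholds[nullRow, band])
  expect_lt(nullExc, 0.2)
})

test_that("zero-gain drives leave all pairs at the noise floor", {
  des <- smallDesign(trialDuration = 20, nChannels = 3)
  st <- generateCommonDriveStudy(des, list(driveSpec(10, 4, c(1, 2), 0)),
                                 seed = 8)
  env <- highpassRectify(st)
  pool <- poolCoherence(lapply(env@trials, welchCoherency, fs = 2000))
  thr <- surrogateThreshold(env@trials, fs = 2000, nSurrogates = 60,
                            seed = 9)
  f <- frequencies(pool)
  keep <- f >= 1 & f <= 60
  exceed <- mean(connectivityValues(pool)[, keep] > thr$thresholds[, keep])
  expect_lt(exceed, 0.10)
})

test_that("excessive modulation depth is rejected", {
  des <- smallDesign(trialDuration = 5, nChannels = 2)
  expect_error(
    generateCommonDriveStudy(des, list(driveSpec(10, 4, 1:2, 2.5)), seed = 1),
    "modulation depth")
  expect_error(
    generateCommonDriveStudy(des, list(driveSpec(10, 4, 5, 0.5)), seed = 1),
    "exceed")
})

test_that("study generation is reproducible byte-for-byte", {
  des <- smallDesign(trialDuration = 2, nChannels = 3,
                     trialsPerCondition = 2)
  drv <- list(driveSpec(10, 4, c(1, 3), 0.5))
  s1 <- generateCommonDriveStudy(des, drv, seed = 7)
  s2 <- generateCommonDriveStudy(des, drv, seed = 7)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  A <- list(diag(0.5, 3))
  cp <- varCouplingSpec(A, diag(3))
  v1 <- generateVarEnvelopeStudy(des, cp, seed = 7)
  v2 <- generateVarEnvelopeStudy(des, cp, seed = 7)
  expect_identical(serialize(v1, NULL), serialize(v2, NULL))
})

test_that("planted PDC ground truth has the coupling zero-structure", {
  # only 1 -> 2 coupling: no 2 -> 1 PDC at any frequency
  A <- list(matrix(c(0.5, 0, 0.4, 0.3), 2, 2, byrow = TRUE))
  pdc <- pdcFromCoefficients(A, seq(0, 100, by = 1), 200)
  expect_equal(max(Mod(pdc$values[1, 2, ])), 0)
  expect_gt(min(Mod(pdc$values[2, 1, ])), 0)
  # diagonal coefficients: no off-diagonal PDC at all
  Ad <- list(diag(0.4, 3), diag(-0.2, 3))
  pd <- pdcFromCoefficients(Ad, seq(0, 100, by = 2), 200)
  off <- pd$values
  for (i in 1:3) off[i, i, ] <- 0
  expect_equal(max(Mod(off)), 0)
})

test_that("var-envelope studies carry a usable directed ground truth", {
  des <- smallDesign(trialDuration = 60, nChannels = 3,
                     trialsPerCondition = 1)
  A <- list(diag(0.9, 3), diag(-0.15, 3))
  A[[1]][2, 1] <- 0.25
  A[[1]][3, 2] <- 0.25
  cp <- varCouplingSpec(A, diag(3))
  freqs <- seq(0, 60, by = 0.5)
  devs <- vapply(1:3, function(s) {
    st <- generateVarEnvelopeStudy(des, cp, seed = s)
    tru <- pdcFromCoefficients(st@provenance$scaledA, freqs, 200)
    x <- trialData(conditionForMvar(highpassRectify(st)), 1)
    fit <- fitMvar(x, selectOrderAic(x, 20)$order, 200)
    est <- modelPdc(fit, freqs)
    mean(abs(Mod(est$values)^2 - Mod(tru$values)^2))
  }, 0)
  # fitted squared PDC tracks the planted truth on average across the grid;
  # single-trial magnitudes are attenuated by envelope measurement noise,
  # so pointwise agreement is looser than the grid-average
  expect_lt(stats::median(devs), 0.1)
})
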