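var2Fixture <- function() {
  list(A = list(matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE),
                matrix(c(-0.2, 0, 0.1, -0.1), 2, 2, byrow = TRUE)),
       Sigma = diag(2))
}

test_that("least squares recovers the coefficients of a known VAR(2)", {
  fx <- var2Fixture()
  devs <- vapply(1:5, function(s) {
    set.seed(s)
    x <- musclenet:::simulateVar(12000, fx$A, fx$Sigma)
    fit <- fitMvar(x, 2)
    max(abs(fit@A[[1]] - fx$A[[1]]), abs(fit@A[[2]] - fx$A[[2]]))
  }, 0)
  expect_lt(stats::median(devs), 0.05)
})

test_that("white noise fits to near-zero coefficients and low AIC order", {
  set.seed(41)
  x <- matrix(rnorm(3 * 6000), 3)
  fit <- fitMvar(x, 2)
  # coefficient standard error is ~ 1/sqrt(N) for unit-variance regressors
  expect_lt(max(abs(unlist(fit@A))), 3.5 / sqrt(fit@nSamples))
  orders <- vapply(1:10, function(s) {
    set.seed(100 + s)
    selectOrderAic(matrix(rnorm(3 * 4000), 3), 10)$order
  }, 0L)
  expect_gte(mean(orders <= 3), 0.9)
})

test_that("collinear channels produce a singular-fit error", {
  set.seed(42)
  x <- matrix(rnorm(4000), 1)
  expect_error(fitMvar(rbind(x, x), 2), "singular")
})

test_that("AIC selects near the true order for a VAR(5)", {
  A <- c(list(diag(0.3, 3)), rep(list(matrix(0, 3, 3)), 3),
         list(diag(0.35, 3) + rbind(0, c(0.25, 0, 0), 0)))
  orders <- vapply(1:8, function(s) {
    set.seed(s)
    selectOrderAic(musclenet:::simulateVar(12000, A, diag(3)), 12)$order
  }, 0L)
  expect_gte(mean(orders >= 4 & orders <= 7), 0.9)
  curve <- selectOrderAic(musclenet:::simulateVar(4000, A, diag(3)), 12)$aic
  expect_length(curve, 12)
  expect_true(all(is.finite(curve)))
})

test_that("instantaneous identification matches the closed 2x2 form", {
  fx <- var2Fixture()
  set.seed(43)
  x <- musclenet:::simulateVar(6000, fx$A, fx$Sigma)
  fit <- fitMvar(x, 2)
  # diagonal residual covariance: extended model is unchanged
  fitD <- fit
  fitD@Sigma <- diag(diag(fit@Sigma))
  ext0 <- identifyInstantaneous(fitD)
  expect_equal(max(abs(ext0@B0)), 0)
  expect_equal(ext0@A, fitD@A, tolerance = 1e-12)
  # Sigma = [[1, .5], [.5, 1]] under ordering (1, 2): B0[2,1] = 0.5
  fit2 <- fit
  fit2@Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  ext <- identifyInstantaneous(fit2)
  expect_equal(ext@B0[2, 1], 0.5)
  expect_equal(ext@B0[1, 2], 0)
  expect_lt(max(abs(ext@Sigma - diag(c(1, 0.75)))), 1e-12)
  # reversing the ordering changes B0 but not the implied spectrum
  extR <- identifyInstantaneous(fit2, ordering = c(2, 1))
  expect_false(isTRUE(all.equal(ext@B0, extR@B0)))
  f <- c(2, 10, 40)
  expect_lt(max(Mod(musclenet:::spectralMatrix(fit2, f) -
                      musclenet:::spectralMatrix(ext, f))), 1e-8)
  expect_lt(max(Mod(musclenet:::spectralMatrix(fit2, f) -
                      musclenet:::spectralMatrix(extR, f))), 1e-8)
  bad <- fit
  bad@Sigma <- matrix(c(1, 1, 1, 1), 2)
  expect_error(identifyInstantaneous(bad), "positive definite")
})

test_that("model coherency is unity on the diagonal and zero across blocks", {
  A <- list(rbind(cbind(matrix(c(0.5, 0.2, 0.1, 0.4), 2), matrix(0, 2, 2)),
                  cbind(matrix(0, 2, 2), matrix(c(0.3, -0.1, 0.2, 0.5), 2))))
  mdl <- new("MvarModel", order = 1L, A = A, B0 = NULL, Sigma = diag(4),
             fs = 200, nSamples = 1000L,
             channelLabels = paste0("c", 1:4), ordering = integer())
  freqs <- seq(0, 60, by = 1)
  S <- musclenet:::spectralMatrix(mdl, freqs)
  for (i in 1:4)
    expect_equal(Mod(S[i, i, ] / sqrt(Re(S[i, i, ]) * Re(S[i, i, ]))),
                 rep(1, length(freqs)))
  coh <- modelCoherency(mdl, freqs)
  crossBlock <- pairIndex(coh)[, "from"] %in% 1:2 &
    pairIndex(coh)[, "to"] %in% 3:4
  expect_lt(max(Mod(connectivityValues(coh)[crossBlock, ])), 1e-10)
})

test_that("PDC is column-normalized and matches the 2x2 closed form", {
  fx <- var2Fixture()
  set.seed(44)
  fit <- fitMvar(musclenet:::simulateVar(8000, fx$A, fx$Sigma), 2)
  freqs <- seq(0, 100, by = 0.5)
  pdc <- modelPdc(fit, freqs)
  colSums2 <- apply(Mod(pdc$values)^2, c(2, 3), sum)
  expect_lt(max(abs(colSums2 - 1)), 1e-10)
  # closed form at f = 0 and f = fs/4 for a VAR(1)
  A1 <- matrix(c(0.5, 0, 0.4, 0.3), 2, 2, byrow = TRUE)
  got <- pdcFromCoefficients(list(A1), c(0, 50), 200)
  for (fi in 1:2) {
    z <- exp(-2i * pi * c(0, 50)[fi] * 1 / 200)
    Ab <- diag(2) - A1 * z
    want <- sweep(Ab, 2, sqrt(colSums(Mod(Ab)^2)), "/")
    expect_equal(got$values[, , fi], want, tolerance = 1e-12)
  }
  expect_equal(Mod(got$values[1, 2, ]), c(0, 0))  # no 2 -> 1 coupling
  expect_gt(min(Mod(got$values[2, 1, ])), 0)
})

test_that("pooled PDC keeps column sums below one", {
  fx <- var2Fixture()
  freqs <- seq(0, 60, by = 0.5)
  pdcs <- lapply(1:4, function(s) {
    set.seed(50 + s)
    modelPdc(fitMvar(musclenet:::simulateVar(6000, fx$A, fx$Sigma), 2),
             freqs)
  })
  one <- poolPdc(pdcs[1])
  expect_equal(connectivityValues(one)[1, ],
               Mod(pdcs[[1]]$values[2, 1, ])^2)
  pooled <- poolPdc(pdcs, subject = "S01", condition = "a")
  expect_true(isDirected(pooled))
  expect_equal(nrow(connectivityValues(pooled)), 2)
  # add back the diagonal contribution: total outflow per source <= 1
  for (src in 1:2) {
    diagPart <- Mod(Reduce(`+`, lapply(pdcs, function(p)
      p$values[src, src, ])) / 4)^2
    offPart <- connectivityValues(pooled)[
      pairIndex(pooled)[, "from"] == src, ]
    expect_true(all(diagPart + colSums(rbind(offPart)) <= 1 + 1e-9))
  }
})

test_that("integrated model spectrum approximates the process variance", {
  fx <- var2Fixture()
  set.seed(45)
  x <- musclenet:::simulateVar(60000, fx$A, fx$Sigma)
  fit <- fitMvar(x, 2, fs = 200)
  freqs <- seq(0, 100, length.out = 2001)
  S <- musclenet:::spectralMatrix(fit, freqs)
  # one-sided integral of the two-sided spectral density
  for (ch in 1:2) {
    pwr <- 2 * mean(Re(S[ch, ch, ])) * 100 / 200
    expect_lt(abs(pwr - stats::var(x[ch, ])) / stats::var(x[ch, ]), 0.05)
  }
})

test_that("directed fixtures rank planted edges above absent ones", {
  des <- smallDesign(trialDuration = 30, nChannels = 3)
  A <- list(diag(0.9, 3), diag(-0.15, 3))
  A[[1]][2, 1] <- 0.3
  A[[1]][3, 2] <- 0.3
  cp <- varCouplingSpec(A, diag(3))
  st <- generateVarEnvelopeStudy(des, cp, seed = 12)
  cnd <- conditionForMvar(highpassRectify(st))
  freqs <- seq(0, 60, by = 0.5)
  pooled <- poolPdc(lapply(cnd@trials, function(x)
    modelPdc(fitMvar(x, selectOrderAic(x, 20)$order, 200), freqs)))
  strength <- rowMeans(connectivityValues(pooled)[, freqs <= 20])
  pm <- pairIndex(pooled)
  planted <- (pm[, "from"] == 1 & pm[, "to"] == 2) |
    (pm[, "from"] == 2 & pm[, "to"] == 3)
  expect_gt(testAuc(strength[planted], strength[!planted]), 0.9)
})

test_that("model coherence agrees with Welch coherence on fixtures", {
  des <- smallDesign(trialDuration = 60, nChannels = 3,
                     trialsPerCondition = 1)
  A <- list(diag(0.9, 3), diag(-0.15, 3))
  A[[1]][2, 1] <- 0.25
  A[[1]][3, 2] <- 0.25
  cp <- varCouplingSpec(A, diag(3))
  st <- generateVarEnvelopeStudy(des, cp, seed = 3)
  env <- highpassRectify(st)
  x <- trialData(conditionForMvar(env), 1)
  fit <- fitMvar(x, selectOrderAic(x, 20)$order, 200)
  wp <- poolCoherence(list(welchCoherency(trialData(env, 1), fs = 2000)))
  keep <- frequencies(wp) <= 60
  wf <- frequencies(wp)[keep]
  mc <- modelCoherency(fit, wf)
  mad <- mean(abs(Mod(connectivityValues(mc))^2 -
                    connectivityValues(wp)[, keep]))
  expect_lt(mad, 0.1)
})
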