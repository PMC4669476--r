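test_that("stacking covers all pairs, conditions and subjects exactly once", {
  specs <- list()
  s <- 0
  for (subj in sprintf("S%02d", 1:18))
    for (cond in c("control", "counting", "cup", "height")) {
      s <- s + 1
      specs[[s]] <- makeSpectra(subj, cond, nch = 10, freqs = 0:60,
                                seed = s)
    }
  stk <- stackSpectra(specs)
  expect_equal(dim(stk$V), c(61, 45 * 4 * 18))
  expect_equal(nrow(stk$index), 3240)
  # subject-major, then condition, then pair ordering
  expect_equal(stk$index$subject[1:90], rep("S01", 90))
  expect_equal(stk$index$condition[46:90], rep("counting", 45))
  # round trip recovers every spectrum exactly
  back <- unstackSpectra(stk)
  expect_equal(connectivityValues(back[[1]]),
               connectivityValues(specs[[1]]))
  expect_equal(back[[5]]@condition, specs[[5]]@condition)
  expect_equal(length(back), 72)
})

test_that("directed stacks have 90 rows per condition and subject", {
  specs <- list(makeSpectra("S01", "a", nch = 10, directed = TRUE, seed = 1),
                makeSpectra("S01", "b", nch = 10, directed = TRUE, seed = 2))
  stk <- stackSpectra(specs)
  expect_equal(ncol(stk$V), 180)
  expect_true(stk$directed)
})

test_that("NMF-ALS recovers exact factorizations", {
  set.seed(61)
  W0 <- matrix(runif(30 * 3), 30)
  H0 <- matrix(runif(3 * 40), 3)
  V <- W0 %*% H0
  fit <- nmfAls(V, k = 3, seed = 2)
  expect_lt(fit$error, 1e-6 * norm(V, "F"))
  # rank-1 input with identical columns
  v1 <- matrix(rep(runif(20), 5), 20)
  f1 <- nmfAls(v1, k = 1, seed = 3)
  expect_lt(f1$error, 1e-8 * norm(v1, "F"))
  expect_gt(abs(stats::cor(f1$W[, 1], v1[, 1])), 0.9999)
  expect_error(nmfAls(-V, 1), "nonnegative")
  expect_error(nmfAls(matrix(0, 4, 4), 1), "degenerate")
  expect_error(nmfAls(V, 50), "exceed")
})

test_that("ALS error traces never increase and runs are deterministic", {
  set.seed(62)
  for (rep in 1:5) {
    V <- matrix(runif(25 * 30), 25) + outer(runif(25), runif(30))
    fit <- nmfAls(V, k = 3, nRestarts = 3, seed = rep)
    expect_true(all(diff(fit$errorTrace) <= 1e-9 * fit$errorTrace[1]))
  }
  f1 <- nmfAls(V, k = 3, seed = 9)
  f2 <- nmfAls(V, k = 3, seed = 9)
  expect_identical(f1, f2)
})

test_that("normalization preserves the product and orders by peak", {
  set.seed(63)
  freqs <- 0:60
  W <- matrix(0, 61, 4)
  for (k in seq_len(4))
    W[, k] <- stats::dnorm(freqs, mean = c(40, 3, 16, 9)[k], sd = 2) +
      0.001
  H <- matrix(runif(4 * 10, 0.5, 2), 4)
  fac <- new("NmfFactorization", W = W, H = H, freqs = as.numeric(freqs),
             index = data.frame(from = rep(1, 10), to = rep(2, 10),
                                condition = "a",
                                subject = sprintf("S%02d", 1:10)),
             directed = FALSE, channelLabels = c("m1", "m2"),
             error = 0, errorTrace = c(1, 0), iterations = 1L,
             restart = 1L)
  norm1 <- orderAndNormalize(fac)
  expect_equal(norm1@W %*% norm1@H, W %*% H, tolerance = 1e-12)
  expect_equal(freqs[apply(norm1@W, 2, which.max)], c(3, 9, 16, 40))
  expect_equal(unname(sqrt(colSums(norm1@W^2))), rep(1, 4))
  # zero component dropped with warning
  facZ <- fac
  facZ@W[, 2] <- 0
  expect_warning(normZ <- orderAndNormalize(facZ), "dropped")
  expect_equal(ncol(normZ@W), 3)
})

test_that("column permutation of the stack permutes the loadings", {
  set.seed(64)
  W0 <- cbind(stats::dnorm(0:30, 5, 2), stats::dnorm(0:30, 20, 3))
  H0 <- matrix(runif(2 * 12, 0.2, 1), 2)
  V <- W0 %*% H0
  perm <- sample(ncol(V))
  f1 <- nmfAls(V, k = 2, seed = 4)
  f2 <- nmfAls(V[, perm], k = 2, seed = 4)
  expect_equal(f1$error, f2$error, tolerance = 1e-6)
  p1 <- apply(f1$W, 2, which.max)
  p2 <- apply(f2$W, 2, which.max)
  expect_setequal(p1, p2)
  # loadings match after aligning components by basis peak
  m <- match(p1, p2)
  expect_equal(f2$H[m, order(perm)], f1$H, tolerance = 1e-4)
})

test_that("restart winners agree on basis peak locations", {
  set.seed(65)
  W0 <- cbind(stats::dnorm(0:60, 3, 1.5), stats::dnorm(0:60, 10, 2))
  H0 <- matrix(runif(2 * 30, 0.1, 1), 2)
  V <- W0 %*% H0 + matrix(runif(61 * 30, 0, 1e-3), 61)
  peaks <- lapply(1:3, function(s)
    sort(apply(nmfAls(V, k = 2, nRestarts = 10, seed = s)$W, 2, which.max)))
  expect_lte(max(abs(peaks[[1]] - peaks[[2]])), 1)
  expect_lte(max(abs(peaks[[1]] - peaks[[3]])), 1)
})

test_that("component networks reshape loadings with the right symmetry", {
  specs <- list(makeSpectra("S01", "a", nch = 10, seed = 71),
                makeSpectra("S02", "a", nch = 10, seed = 72))
  fac <- orderAndNormalize(unmixSpectra(stackSpectra(specs), k = 2,
                                        nRestarts = 2, seed = 5))
  nets <- componentNetworks(fac)
  expect_equal(length(nets), 2 * 2)  # K x (conditions x subjects)
  for (nt in nets) {
    A <- adjacencyMatrix(nt)
    expect_equal(A, t(A))
    expect_equal(unname(diag(A)), rep(0, 10))
    expect_gte(min(A), 0)
  }
  # directed loadings fill ordered pairs
  dspecs <- list(makeSpectra("S01", "a", nch = 4, directed = TRUE,
                             seed = 73))
  dfac <- orderAndNormalize(unmixSpectra(stackSpectra(dspecs), k = 2,
                                         nRestarts = 2, seed = 6))
  dnet <- componentNetworks(dfac)[[1]]
  expect_true(isDirected(dnet))
  A <- adjacencyMatrix(dnet)
  pm <- pairIndex(dspecs[[1]])
  expect_equal(A[cbind(pm[, "to"], pm[, "from"])],
               unname(loadingsMatrix(dfac)[1, ]))
})

test_that("two-drive studies unmix into the planted bands and pairs", {
  des <- studyDesign(nSubjects = 2, conditions = "control",
                     trialsPerCondition = 4, trialDuration = 30, fs = 2000,
                     channelLabels = paste0("m", 1:6))
  drives <- list(driveSpec(3, 2, targets = 1:3, gain = 0.5),
                 driveSpec(10, 4, targets = 4:5, gain = 0.5))
  st <- generateCommonDriveStudy(des, drives, seed = 11)
  env <- highpassRectify(st)
  groups <- musclenet:::splitByGroup(env)
  spectra <- lapply(groups, function(g)
    poolCoherence(lapply(g$trials, welchCoherency, fs = 2000),
                  g$subject, g$condition))
  stk <- stackSpectra(spectra)
  fac <- orderAndNormalize(unmixSpectra(stk, k = 2, seed = 5))
  peaks <- stk$freqs[apply(basisMatrix(fac), 2, which.max)]
  expect_lte(abs(peaks[1] - 3), 1)
  expect_lte(abs(peaks[2] - 10), 1)
  idx <- fac@index
  H <- loadingsMatrix(fac)
  planted1 <- idx$from %in% 1:3 & idx$to %in% 1:3
  planted2 <- idx$from %in% 4:5 & idx$to %in% 4:5
  expect_gt(testAuc(H[1, planted1], H[1, !planted1]), 0.9)
  expect_gt(testAuc(H[2, planted2], H[2, !planted2]), 0.9)
})
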