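# Independent brute-force oracles for the weighted graph metrics, written as
# explicit loops / path enumeration so they share no code with the package
# implementations, plus small fixture builders.

# Weighted clustering coefficient by triple enumeration.
bfClustering <- function(A, directed = FALSE) {
  n <- nrow(A)
  mx <- max(A)
  if (mx == 0) return(rep(0, n))
  W <- A / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (!directed) {
      num <- 0
      for (j in seq_len(n)) for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        num <- num + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
      }
      k <- sum(A[i, ] > 0)
      out[i] <- if (k >= 2) num / (k * (k - 1)) else 0
    } else {
      S <- W^(1 / 3) + t(W)^(1 / 3)
      num <- 0
      for (j in seq_len(n)) for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        num <- num + S[i, j] * S[j, h] * S[h, i]
      }
      num <- num / 2
      ktot <- sum(A[i, ] > 0) + sum(A[, i] > 0)
      kbi <- sum(A[i, ] > 0 & A[, i] > 0)
      den <- ktot * (ktot - 1) - 2 * kbi
      out[i] <- if (den > 0) num / den else 0
    }
  }
  out
}

# All simple paths s -> t on an adjacency with lengths 1/weight; returns a
# list of integer node sequences. `A` follows the package convention
# A[target, source], so an edge from u to v requires A[v, u] > 0.
bfAllPaths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (A[v, u] > 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  paths
}

bfPathLength <- function(A, path) {
  sum(vapply(seq_len(length(path) - 1L), function(i)
    1 / A[path[i + 1L], path[i]], 0))
}

# Global efficiency and betweenness by exhaustive path enumeration.
bfPathMetrics <- function(A, directed = FALSE) {
  n <- nrow(A)
  Au <- if (directed) A else pmax(A, t(A))
  geSum <- 0
  bc <- numeric(n)
  pairs <- if (directed) {
    which(outer(seq_len(n), seq_len(n), "!="), arr.ind = TRUE)
  } else {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  for (r in seq_len(nrow(pairs))) {
    s <- pairs[r, 1L]; t <- pairs[r, 2L]
    ps <- bfAllPaths(Au, s, t)
    if (length(ps) == 0L) next
    lens <- vapply(ps, function(p) bfPathLength(Au, p), 0)
    dmin <- min(lens)
    geSum <- geSum + 1 / dmin
    if (!directed) geSum <- geSum + 1 / dmin  # both orders for GE
    short <- ps[lens <= dmin * (1 + 1e-10)]
    through <- numeric(n)
    for (p in short) {
      mid <- p[-c(1L, length(p))]
      through[mid] <- through[mid] + 1
    }
    bc <- bc + through / length(short)
  }
  list(ge = geSum / (n * (n - 1)), bc = bc)
}

randomGraph <- function(n, directed = FALSE, density = 0.6) {
  A <- matrix(0, n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  w <- matrix(stats::runif(n * n, 0.2, 1), n, n)
  A[mask] <- w[mask]
  diag(A) <- 0
  if (!directed) {
    A[lower.tri(A)] <- 0
    A <- A + t(A)
  }
  A
}

# ConnectivitySpectra with reproducible random nonnegative values.
makeSpectra <- function(subject, condition, nch = 10, freqs = 0:60,
                        directed = FALSE, seed = 1L) {
  set.seed(seed)
  pairs <- enumeratePairs(nch, directed)
  vals <- matrix(stats::runif(nrow(pairs) * length(freqs), 0, 0.8),
                 nrow(pairs))
  new("ConnectivitySpectra", values = vals, freqs = as.numeric(freqs),
      pairs = pairs, directed = directed, subject = subject,
      condition = condition, channelLabels = paste0("ch", seq_len(nch)))
}

# Rank-based AUC (Wilcoxon), independent of the package helper.
testAuc <- function(pos, neg) {
  stats::wilcox.test(pos, neg)$statistic / (length(pos) * length(neg))
}

# Small study designs used across tests.
smallDesign <- function(nSubjects = 1, conditions = "control",
                        trialsPerCondition = 4, trialDuration = 30,
                        nChannels = 4, fs = 2000) {
  studyDesign(nSubjects = nSubjects, conditions = conditions,
              trialsPerCondition = trialsPerCondition,
              trialDuration = trialDuration, fs = fs,
              channelLabels = paste0("m", seq_len(nChannels)))
}
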