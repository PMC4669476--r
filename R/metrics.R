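adjOf <- function(network) {
  if (is(network, "MuscleNetwork")) network@adjacency
  else if (is.matrix(network)) network
  else stop("expected a MuscleNetwork or adjacency matrix")
}

dirOf <- function(network, directed) {
  if (is(network, "MuscleNetwork")) network@directed
  else isTRUE(directed)
}

# igraph representation on edge lengths 1/weight; zero-weight edges are
# absent (infinite length). Our directed adjacency stores A[target, source],
# igraph expects row -> column, hence the transpose.
asLengthGraph <- function(A, directed) {
  L <- A
  L[A > 0] <- 1 / A[A > 0]
  L[A == 0] <- 0
  igraph::graph_from_adjacency_matrix(
    if (directed) t(L) else L,
    mode = if (directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering coefficient with weights normalized by the
#' network's maximum weight. Undirected networks use the geometric-mean
#' (Onnela) form `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`;
#' directed networks use its directed generalization counting all triangle
#' orientations, `C_i = [(W^(1/3) + (W^T)^(1/3))^3]_ii /
#' (2 [k_tot (k_tot - 1) - 2 k_bidir])`. Nodes with fewer than two neighbours
#' get `C_i = 0`. Values lie in [0, 1].
#'
#' @param network a [MuscleNetwork-class] or nonnegative adjacency matrix
#'   with zero diagonal.
#' @param directed used only for matrix input.
#' @return list with `perNode` and `mean`.
#' @export
clusteringCoefficient <- function(network, directed = FALSE) {
  A <- adjOf(network)
  directed <- dirOf(network, directed)
  if (any(A < 0)) stop("weights must be nonnegative")
  n <- nrow(A)
  mx <- max(A)
  if (mx == 0)
    return(list(perNode = rep(0, n), mean = 0))
  W3 <- (A / mx)^(1 / 3)
  B <- (A > 0) * 1
  if (!directed) {
    tri <- diag(W3 %*% W3 %*% W3)
    k <- rowSums(B)
    denom <- k * (k - 1)
  } else {
    Ws <- W3 + t(W3)
    tri <- diag(Ws %*% Ws %*% Ws) / 2
    ktot <- rowSums(B) + colSums(B)
    kbi <- diag(B %*% B)
    denom <- ktot * (ktot - 1) - 2 * kbi
  }
  cc <- ifelse(denom > 0, tri / denom, 0)
  list(perNode = as.numeric(cc), mean = mean(cc))
}

#' Weighted global efficiency
#'
#' Mean inverse weighted shortest-path length over all ordered node pairs,
#' with edge lengths `1/weight` (zero-weight edges are absent, i.e. have
#' infinite length); disconnected pairs contribute 0. Directed networks use
#' directed paths.
#'
#' @inheritParams clusteringCoefficient
#' @return scalar global efficiency.
#' @export
globalEfficiency <- function(network, directed = FALSE) {
  A <- adjOf(network)
  directed <- dirOf(network, directed)
  if (any(A < 0)) stop("weights must be nonnegative")
  n <- nrow(A)
  if (n < 2 || max(A) == 0) return(0)
  g <- asLengthGraph(A, directed)
  d <- igraph::distances(g, mode = if (directed) "out" else "all",
                         weights = igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted betweenness centrality
#'
#' Fraction-weighted shortest-path betweenness (Brandes) on edge lengths
#' `1/weight`: each node's score accumulates, over all source-target pairs,
#' the fraction of equal-length shortest paths passing through it.
#' Unnormalized by default; undirected networks count each unordered pair
#' once, directed networks use directed paths over ordered pairs.
#'
#' @inheritParams clusteringCoefficient
#' @param normalize divide by the number of possible source-target pairs.
#' @return list with `perNode` and `mean`.
#' @export
betweennessCentrality <- function(network, directed = FALSE,
                                  normalize = FALSE) {
  A <- adjOf(network)
  directed <- dirOf(network, directed)
  if (any(A < 0)) stop("weights must be nonnegative")
  n <- nrow(A)
  if (n < 3 || max(A) == 0)
    return(list(perNode = rep(0, n), mean = 0))
  g <- asLengthGraph(A, directed)
  bc <- igraph::betweenness(g, directed = directed,
                            weights = igraph::E(g)$weight)
  bc <- as.numeric(bc)
  if (normalize) {
    denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
    bc <- bc / denom
  }
  list(perNode = bc, mean = mean(bc))
}

#' All three network metrics for one network
#'
#' Convenience wrapper returning the mean clustering coefficient, global
#' efficiency and mean betweenness centrality (always computed on the full
#' weighted matrix; thresholding is for visualization only).
#'
#' @inheritParams clusteringCoefficient
#' @return named list `cc`, `ge`, `bc` (scalars).
#' @export
networkMetrics <- function(network, directed = FALSE) {
  list(cc = clusteringCoefficient(network, directed)$mean,
       ge = globalEfficiency(network, directed),
       bc = betweennessCentrality(network, directed)$mean)
}

#' Tidy metric table for a list of networks
#'
#' @param networks list of [MuscleNetwork-class].
#' @return data.frame with subject, condition, component, directed, CC, GE,
#'   BC -- the input for [rmAnova()].
#' @export
metricsTable <- function(networks) {
  do.call(rbind, lapply(networks, function(nt) {
    m <- networkMetrics(nt)
    data.frame(subject = nt@subject, condition = nt@condition,
               component = nt@component, directed = nt@directed,
               CC = m$cc, GE = m$ge, BC = m$bc, stringsAsFactors = FALSE)
  }))
}

#' Proportional threshold (binarisation for visualization)
#'
#' Keeps the strongest `ceiling(keepFraction * n_candidates)` edges, where
#' the candidates are all off-diagonal slots (unordered pairs for
#' undirected networks, ordered pairs for directed ones), and binarises
#' them. Ties at the cut-off weight are resolved deterministically by
#' pair-enumeration order (earlier pair wins). Kept slots with zero weight
#' remain absent. For visualization only: metrics always use the weighted
#' matrices.
#'
#' @param network a [MuscleNetwork-class] or adjacency matrix.
#' @param keepFraction fraction of candidate edges to keep, in (0, 1].
#' @param directed used only for matrix input.
#' @return object of the same kind with a binary (0/1) adjacency.
#' @export
proportionalThreshold <- function(network, keepFraction, directed = FALSE) {
  if (!(keepFraction > 0 && keepFraction <= 1))
    stop("keepFraction must be in (0, 1]")
  A <- adjOf(network)
  directed <- dirOf(network, directed)
  pairs <- enumeratePairs(nrow(A), directed)
  w <- A[cbind(pairs[, "to"], pairs[, "from"])]
  nKeep <- ceiling(keepFraction * nrow(pairs))
  ord <- order(-w, seq_along(w))
  keep <- ord[seq_len(nKeep)]
  B <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  kept <- pairs[keep, , drop = FALSE]
  pos <- w[keep] > 0
  B[cbind(kept[pos, "to"], kept[pos, "from"])] <- 1
  if (!directed) B[cbind(kept[pos, "from"], kept[pos, "to"])] <- 1
  if (is(network, "MuscleNetwork")) {
    network@adjacency <- B
    validObject(network)
    network
  } else B
}
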