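# Orthonormal contrast matrix (levels x (levels-1)) spanning the
# complement of the constant vector.
orthoContrasts <- function(a) {
  qr.Q(qr(cbind(1, stats::contr.helmert(a))))[, -1L, drop = FALSE]
}

# Mauchly sphericity test and epsilon estimates on a subjects x cells
# matrix Y under contrast matrix C (cells x k). Returns W/p = NA (epsilons
# 1) when the test is not defined (k = 1 or too few subjects).
sphericityStats <- function(Y, C) {
  n <- nrow(Y)
  k <- ncol(C)
  Z <- Y %*% C
  if (k < 2L || n - 1L <= k)
    return(list(W = NA_real_, p = NA_real_, gg = 1, hf = 1))
  S <- stats::cov(Z)
  tr <- sum(diag(S))
  if (tr <= 0 || sum(S^2) == 0)  # degenerate (constant) data
    return(list(W = NA_real_, p = NA_real_, gg = 1, hf = 1))
  gg <- tr^2 / (k * sum(S^2))
  hf <- (n * k * gg - 2) / (k * (n - 1 - k * gg))
  W <- det(S) / (tr / k)^k
  # chi-square approximation with Box's second-order correction term
  nu <- n - 1
  d <- 1 - (2 * k^2 + k + 2) / (6 * k * nu)
  w2 <- (k + 2) * (k - 1) * (k - 2) * (2 * k^3 + 6 * k^2 + 3 * k + 2) /
    (288 * (nu * k * d)^2)
  stat <- -nu * d * log(W)
  df <- k * (k + 1) / 2 - 1
  p1 <- stats::pchisq(stat, df, lower.tail = FALSE)
  p2 <- stats::pchisq(stat, df + 4, lower.tail = FALSE)
  list(W = W, p = p1 + w2 * (p2 - p1), gg = gg, hf = hf)
}

#' Condition x frequency repeated-measures ANOVA
#'
#' Two-way fully within-subject ANOVA by standard sum-of-squares
#' partitioning (each effect tested against its subject-interaction error
#' term), with Mauchly's sphericity test per effect and the Huynh-Feldt
#' correction of degrees of freedom applied when Mauchly's p < 0.05. Both
#' uncorrected and corrected p-values are reported; epsilons are clipped to
#' at most 1 and the sphericity test is skipped (epsilon = 1) for two-level
#' effects, where sphericity holds trivially.
#'
#' @param table data.frame with columns `subject`, `condition`, `component`
#'   and the response named by `value`; the design must be completely
#'   crossed with one observation per cell and at least 3 subjects.
#' @param value name of the response column.
#' @param alpha Mauchly significance threshold that triggers the correction.
#' @return data.frame of class `AnovaResult`, one row per effect
#'   (condition, component, condition:component) with F, dfs, Mauchly W and
#'   p, Greenhouse-Geisser and Huynh-Feldt epsilons, corrected dfs, and
#'   uncorrected/corrected p-values.
#' @export
rmAnova <- function(table, value = "value", alpha = 0.05) {
  need <- c("subject", "condition", "component", value)
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  subj <- unique(table$subject)
  A <- unique(table$condition)
  B <- unique(table$component)
  n <- length(subj); a <- length(A); b <- length(B)
  if (n < 3) stop("need at least 3 subjects")
  if (nrow(table) != n * a * b)
    stop("incomplete design: expected one row per subject x condition x component cell")
  Y <- array(NA_real_, dim = c(n, a, b))
  idx <- cbind(match(table$subject, subj), match(table$condition, A),
               match(table$component, B))
  if (anyDuplicated(idx)) stop("duplicate cells in the design")
  Y[idx] <- table[[value]]
  if (anyNA(Y)) stop("incomplete design: missing cells")

  g <- mean(Y)
  mS <- apply(Y, 1L, mean); mA <- apply(Y, 2L, mean); mB <- apply(Y, 3L, mean)
  mSA <- apply(Y, c(1L, 2L), mean); mSB <- apply(Y, c(1L, 3L), mean)
  mAB <- apply(Y, c(2L, 3L), mean)

  ssA <- n * b * sum((mA - g)^2)
  ssB <- n * a * sum((mB - g)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1L, mA), 2L, mB) + g)^2)
  ssAS <- b * sum((sweep(sweep(mSA, 1L, mS), 2L, mA) + g)^2)
  ssBS <- a * sum((sweep(sweep(mSB, 1L, mS), 2L, mB) + g)^2)
  fit <- array(0, dim = dim(Y))
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b))
    fit[i, j, l] <- mAB[j, l] + mSA[i, j] + mSB[i, l] -
      mA[j] - mB[l] - mS[i] + g
  ssABS <- sum((Y - fit)^2)

  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB
  dfAS <- dfA * (n - 1); dfBS <- dfB * (n - 1); dfABS <- dfAB * (n - 1)

  CA <- orthoContrasts(a); CB <- orthoContrasts(b)
  sphA <- sphericityStats(mSA, CA)
  sphB <- sphericityStats(mSB, CB)
  YAB <- matrix(aperm(Y, c(1L, 3L, 2L)), n)  # cells ordered B within A
  sphAB <- sphericityStats(YAB, kronecker(CA, CB))

  one <- function(label, ss, df1, ssErr, df2, sph) {
    Fv <- if (ss <= 0) 0 else (ss / df1) / (ssErr / df2)
    if (!is.finite(Fv)) Fv <- 0
    gg <- min(sph$gg, 1); hf <- min(sph$hf, 1)
    applyCorr <- is.finite(sph$p) && sph$p < alpha
    eps <- if (applyCorr) hf else 1
    data.frame(effect = label, F = Fv, df1 = df1, df2 = df2,
               mauchlyW = sph$W, mauchlyP = sph$p,
               epsilonGG = gg, epsilonHF = hf,
               df1Corrected = eps * df1, df2Corrected = eps * df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               pHF = stats::pf(Fv, hf * df1, hf * df2, lower.tail = FALSE),
               pCorrected = stats::pf(Fv, eps * df1, eps * df2,
                                      lower.tail = FALSE),
               correctionApplied = applyCorr,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("condition", ssA, dfA, ssAS, dfAS, sphA),
               one("component", ssB, dfB, ssBS, dfBS, sphB),
               one("condition:component", ssAB, dfAB, ssABS, dfABS, sphAB))
  class(out) <- c("AnovaResult", class(out))
  out
}

#' Paired post-hoc t-tests
#'
#' Two-sided paired t-tests across subjects for the requested level pairs of
#' a within-subject factor, averaging over the other factor first. Degrees of
#' freedom are `n_subjects - 1`. No multiple-comparison correction by
#' default.
#'
#' @param table as in [rmAnova()].
#' @param value name of the response column.
#' @param effect factor to compare: `"condition"` or `"component"`.
#' @param comparisons two-column matrix (or list of length-2 vectors) of
#'   level pairs; default all unordered level pairs.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame with levelA, levelB, t, df, p (and pAdjusted when
#'   `adjust != "none"`).
#' @export
pairedPosthoc <- function(table, value = "value",
                          effect = c("condition", "component"),
                          comparisons = NULL, adjust = "none") {
  effect <- match.arg(effect)
  levs <- unique(table[[effect]])
  agg <- stats::aggregate(table[[value]],
                          by = list(subject = table$subject,
                                    level = table[[effect]]),
                          FUN = mean)
  if (is.null(comparisons)) {
    cmb <- utils::combn(levs, 2L)
    comparisons <- t(cmb)
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  res <- apply(comparisons, 1L, function(cmp) {
    if (!all(cmp %in% levs))
      stop("unknown level(s): ", paste(setdiff(cmp, levs), collapse = ", "))
    xa <- agg$x[agg$level == cmp[1L]][order(agg$subject[agg$level == cmp[1L]])]
    xb <- agg$x[agg$level == cmp[2L]][order(agg$subject[agg$level == cmp[2L]])]
    d <- xa - xb
    n <- length(d)
    if (stats::sd(d) == 0) {
      c(t = 0, df = n - 1, p = 1)
    } else {
      tt <- stats::t.test(xa, xb, paired = TRUE)
      c(t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  })
  out <- data.frame(levelA = comparisons[, 1L], levelB = comparisons[, 2L],
                    t = res["t", ], df = res["df", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  if (adjust != "none") out$pAdjusted <- stats::p.adjust(out$p, adjust)
  out
}
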