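#' Welch two-sample t-test
#'
#' Unpaired t statistic with Welch-Satterthwaite degrees of freedom,
#' \eqn{t = (\bar x_B - \bar x_A)/\sqrt{s_A^2/n_A + s_B^2/n_B}}, two-sided
#' p from the t distribution. The effect orientation is group B minus
#' group A.
#'
#' Degenerate inputs never abort a full-matrix run: when both groups have
#' zero variance the p-value is 1 (equal means, t = 0) or the smallest
#' representable positive double (unequal means), and the case is logged.
#'
#' @param xA,xB numeric vectors of log2 values, each of length >= 2.
#' @return list with \code{t_stat}, \code{df}, \code{p}.
#' @examples
#' welchT(c(0.9, 1.1, 1.0), c(2.0, 2.2, 1.8))
#' @export
welchT <- function(xA, xB) {
  if (length(xA) < 2 || length(xB) < 2)
    stopFmt("welchT needs >= 2 values per group")
  r <- welchRows(matrix(xA, nrow = 1), matrix(xB, nrow = 1))
  list(t_stat = r$t[1], df = r$df[1], p = r$p[1])
}

rowVarsM <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

## vectorised Welch over row-matched matrices; the scalar API wraps this
welchRows <- function(mA, mB) {
  nA <- ncol(mA); nB <- ncol(mB)
  muA <- rowMeans(mA); muB <- rowMeans(mB)
  vA <- rowVarsM(mA); vB <- rowVarsM(mB)
  seA <- vA / nA; seB <- vB / nB
  se2 <- seA + seB
  delta <- muB - muA
  t <- delta / sqrt(se2)
  df <- se2^2 / (seA^2 / (nA - 1) + seB^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & delta == 0
    ne <- degen & delta != 0
    t[eq] <- 0; df[eq] <- nA + nB - 2; p[eq] <- 1
    t[ne] <- sign(delta[ne]) * Inf
    df[ne] <- nA + nB - 2
    p[ne] <- .Machine$double.xmin
    xcLog(sum(degen), " zero-variance gene(s) in Welch test (sentinel p)")
  }
  list(delta = delta, t = t, df = df, p = p)
}

#' Paired t-test on per-pair differences
#'
#' \eqn{t = \bar d / (s_d/\sqrt n)}, df = n - 1, two-sided p. A
#' zero-variance difference vector yields p = 1 (zero mean) or the smallest
#' representable positive double (nonzero mean), logged.
#'
#' @param diffs numeric vector of per-pair log2 differences, length >= 2.
#' @return list with \code{t_stat}, \code{df}, \code{p}.
#' @export
pairedT <- function(diffs) {
  if (length(diffs) < 2) stopFmt("pairedT needs >= 2 pairs")
  r <- pairedRows(matrix(diffs, nrow = 1))
  list(t_stat = r$t[1], df = r$df[1], p = r$p[1])
}

pairedRows <- function(d) {
  n <- ncol(d)
  mu <- rowMeans(d)
  s <- sqrt(rowVarsM(d))
  t <- mu / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  degen <- s == 0
  if (any(degen)) {
    eq <- degen & mu == 0
    ne <- degen & mu != 0
    t[eq] <- 0; p[eq] <- 1
    t[ne] <- sign(mu[ne]) * Inf
    p[ne] <- .Machine$double.xmin
    xcLog(sum(degen), " zero-variance gene(s) in paired test (sentinel p)")
  }
  list(delta = mu, t = t, df = rep(df, nrow(d)), p = p)
}

#' Classical one-way ANOVA
#'
#' F statistic and p-value for equality of group means, pooled
#' within-group variance. A gene with zero within- and between-group
#' variance yields p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with \code{F_stat}, \code{df1}, \code{df2}, \code{p}.
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2) stopFmt("anovaOneway needs >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stopFmt("each group needs >= 2 values")
  m <- matrix(unlist(groups), nrow = 1)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  r <- anovaRows(m, g)
  list(F_stat = r$F[1], df1 = r$df1, df2 = r$df2, p = r$p[1])
}

anovaRows <- function(m, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- ncol(m)
  counts <- as.vector(table(g))
  gmean <- rowsum(t(m), g) / counts   # k x genes group means
  grand <- rowMeans(m)
  dev <- gmean - matrix(grand, nrow = k, ncol = nrow(m), byrow = TRUE)
  ssb <- as.vector(colSums(counts * dev^2))
  sst <- rowSums((m - grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  msw <- ssw / df2
  Fst <- (ssb / df1) / msw
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  degen <- msw <= 0
  if (any(degen)) {
    null0 <- degen & ssb <= 1e-300
    Fst[null0] <- 0; p[null0] <- 1
    sig <- degen & !null0
    Fst[sig] <- Inf; p[sig] <- .Machine$double.xmin
    xcLog(sum(degen), " zero-variance gene(s) in ANOVA (sentinel p)")
  }
  list(F = Fst, df1 = df1, df2 = df2, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Definition-level step-up FDR adjustment: \eqn{p_{(i)} m / i}, cumulative
#' minimum from the largest p down, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  checkP(p)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

checkP <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopFmt("p-values must lie in [0, 1]")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.90 via \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))},
#' smoothed with a cubic smoothing spline and evaluated at lambda = 0.90,
#' clamped to (0, 1]. q-values are the step-up quantity
#' \eqn{\min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)},
#' monotone in p and capped at 1. With pi0 = 1 this reduces exactly to
#' [bhAdjust()].
#'
#' Below 100 p-values the smoother is unreliable and pi0 is fixed at 1
#' (logged).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return list with \code{q} (same order as input) and \code{pi0}.
#' @export
storeyQvalues <- function(p) {
  checkP(p)
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), pi0 = 1))
  if (m < 100) {
    xcLog("fewer than 100 p-values: pi0 fixed at 1")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.90, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 1.0)
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = 0.90)$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  list(q = pmin(1, pi0 * bhAdjust(p)), pi0 = pi0)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return list with \code{r} and two-sided \code{p} (df = n - 2).
#' @export
pearsonR <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stopFmt("pearsonR needs equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopFmt("pearsonR: constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities not exceeding that of the observed table (relative
#' tolerance 1e-7), computed in log space so large counts do not overflow.
#' A zero margin makes the table degenerate and returns p = 1 (logged).
#'
#' @param tab 2x2 matrix of nonnegative integer counts, or a length-4
#'   vector (a, b, c, d) filling the table by row.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(c(3, 0, 0, 3))  # 0.1
#' @export
fisherExact2x2 <- function(tab) {
  if (is.matrix(tab)) tab <- as.vector(t(tab))
  if (length(tab) != 4 || any(tab < 0) || any(tab != round(tab)))
    stopFmt("fisherExact2x2 needs four nonnegative integer counts")
  a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  n <- a + b + c + d
  if (n < 1) stopFmt("empty table")
  m1 <- a + b; n1 <- a + c
  if (m1 == 0 || m1 == n || n1 == 0 || n1 == n) {
    xcLog("degenerate 2x2 table (zero margin): p = 1")
    return(1)
  }
  ks <- max(0, n1 - (n - m1)):min(m1, n1)
  logp <- lchoose(m1, ks) + lchoose(n - m1, n1 - ks) - lchoose(n, n1)
  obs <- logp[ks == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Rank-sum comparison of one category against the rest of a ranked list
#'
#' Compares the ranks of in-category genes with those of the remaining
#' genes of one common ranked list (average ranks for ties). For total
#' list length <= 12 the null distribution of the in-category rank sum is
#' enumerated exactly over all subsets; otherwise a normal approximation
#' with tie correction and continuity correction is used. The two-sided p
#' is \code{min(1, 2 * min(lower tail, upper tail))}.
#'
#' The direction sign is +1 when the in-category mean rank lies toward the
#' top of the ranking (rank 1 = strongest increase), -1 toward the bottom;
#' an exact mean-rank tie yields +1.
#'
#' @param inRanks,outRanks numeric rank vectors from one common list; both
#'   nonempty.
#' @param exactLimit total list length at or below which the exact
#'   enumeration is used (default 12).
#' @return list with \code{W} (in-category rank sum), \code{p} (two-sided),
#'   \code{pLower}, \code{pUpper} (one-sided tails), \code{sign},
#'   \code{method}.
#' @export
wilcoxonRank <- function(inRanks, outRanks, exactLimit = 12) {
  nIn <- length(inRanks); nOut <- length(outRanks)
  if (nIn == 0 || nOut == 0) stopFmt("both rank groups must be nonempty")
  allR <- c(inRanks, outRanks)
  N <- nIn + nOut
  w <- sum(inRanks)
  if (N <= exactLimit) {
    sets <- utils::combn(N, nIn)
    sums <- colSums(matrix(allR[sets], nrow = nIn))
    tol <- 1e-9
    pLower <- mean(sums <= w + tol)
    pUpper <- mean(sums >= w - tol)
    method <- "exact"
  } else {
    e <- nIn * (N + 1) / 2
    s2 <- sum(allR^2)
    v <- nIn * nOut / (N * (N - 1)) * (s2 - N * (N + 1)^2 / 4)
    if (v <= 0) return(list(W = w, p = 1, pLower = 1, pUpper = 1,
                            sign = 1, method = "normal"))
    pLower <- stats::pnorm((w - e + 0.5) / sqrt(v))
    pUpper <- stats::pnorm((w - e - 0.5) / sqrt(v), lower.tail = FALSE)
    method <- "normal"
  }
  p <- min(1, 2 * min(pLower, pUpper))
  sgn <- if (mean(inRanks) <= mean(outRanks)) 1 else -1
  list(W = w, p = p, pLower = pLower, pUpper = pUpper,
       sign = sgn, method = method)
}
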