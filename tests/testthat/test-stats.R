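test_that("Welch t matches its closed-form special cases", {
  r <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p, 1)

  ## equal n and equal sample variances collapse df to nA + nB - 2
  xA <- c(1, 2, 3); xB <- c(5, 6, 7)
  expect_equal(welchT(xA, xB)$df, 4)
})

test_that("Welch t, paired t and ANOVA agree with base R to 1e-10", {
  xA <- c(0.9, 1.1, 1.0); xB <- c(2.0, 2.2, 1.8)
  r <- welchT(xA, xB)
  ref <- t.test(xB, xA)
  expect_equal(r$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)

  d <- c(0.8, 1.2, 1.0, 0.6)
  rp <- pairedT(d)
  refp <- t.test(d)
  expect_equal(rp$t_stat, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(rp$p, refp$p.value, tolerance = 1e-10)

  g <- list(c(1, 2), c(3, 4), c(5, 6))
  ra <- anovaOneway(g)
  dat <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 2)))
  refa <- summary(stats::aov(y ~ f, dat))[[1]]
  expect_equal(ra$F_stat, refa[["F value"]][1], tolerance = 1e-10)
  expect_equal(ra$p, refa[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5, 1)
    ra <- anovaOneway(list(a, b))
    rt <- t.test(a, b, var.equal = TRUE)
    expect_equal(ra$F_stat, unname(rt$statistic)^2, tolerance = 1e-10)
    expect_equal(ra$p, rt$p.value, tolerance = 1e-10)
  }
})

test_that("two-sided tests are invariant under group-label swap", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(4)
    expect_equal(welchT(a, b)$p, welchT(b, a)$p, tolerance = 1e-12)
    expect_equal(welchT(a, b)$t_stat, -welchT(b, a)$t_stat, tolerance = 1e-12)
    expect_equal(anovaOneway(list(a, b))$p, anovaOneway(list(b, a))$p,
                 tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance inputs give sentinel p-values", {
  r <- welchT(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r$p, 1)
  r2 <- welchT(c(1, 1, 1), c(2, 2, 2))
  expect_equal(r2$p, .Machine$double.xmin)
  expect_equal(pairedT(c(0.5, -0.5))$p, 1)
  expect_equal(pairedT(c(1, 1, 1, 1))$p, .Machine$double.xmin)
  expect_equal(anovaOneway(list(c(1, 1), c(1, 1)))$p, 1)
})

test_that("BH step-up matches the worked example and p.adjust", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey q-values reduce to BH at pi0 = 1 and respect monotonicity", {
  expect_equal(storeyQvalues(rep(1, 150))$pi0, 1)
  expect_true(all(storeyQvalues(rep(1, 150))$q == 1))
  ## below 100 p-values pi0 is fixed at 1 so q == BH exactly
  set.seed(12)
  p <- runif(60)
  s <- storeyQvalues(p)
  expect_equal(s$pi0, 1)
  expect_equal(s$q, bhAdjust(p))
  ## q <= BH always (pi0 <= 1) and q monotone in p
  p2 <- c(runif(300), rbeta(200, 0.5, 6))
  s2 <- storeyQvalues(p2)
  expect_true(all(s2$q <= bhAdjust(p2) + 1e-12))
  o <- order(p2)
  expect_true(all(diff(s2$q[o]) >= -1e-12))
})

test_that("Pearson correlation matches cor.test to 1e-12", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -2 * x)$r, -1)
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10)
  r <- pearsonR(a, b)
  ref <- cor.test(a, b)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonR(rep(1, 5), rnorm(5)), "constant")
})

test_that("Fisher exact matches enumeration and base R on random tables", {
  expect_equal(fisherExact2x2(c(1, 0, 0, 1)), 1)
  expect_equal(fisherExact2x2(c(3, 0, 0, 3)), 0.1, tolerance = 1e-12)
  expect_equal(fisherExact2x2(c(5, 0, 2, 0)), 1)  # zero margin
  set.seed(14)
  for (i in 1:100) {
    t4 <- rpois(4, sample(c(2, 8, 40), 1))
    if (sum(t4) == 0) next
    mine <- fisherExact2x2(t4)
    expect_equal(mine, oracleFisher(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-9)
    m <- matrix(t4, 2, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0))
      expect_equal(mine, fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant under transposing the table", {
  set.seed(15)
  for (i in 1:30) {
    m <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisherExact2x2(m), fisherExact2x2(t(m)), tolerance = 1e-12)
  }
})

test_that("rank-sum exact tail matches the top-2-of-5 enumeration", {
  w <- wilcoxonRank(c(1, 2), c(3, 4, 5))
  expect_equal(w$pLower, 0.1)     # 1 / choose(5, 2)
  expect_equal(w$p, 0.2)          # two-sided
  expect_equal(w$sign, 1)
})

test_that("a perfectly interleaved category is non-significant with tie-break sign", {
  w <- wilcoxonRank(c(1, 4), c(2, 3))
  expect_true(w$p > 0.6)
  expect_equal(w$sign, 1)         # equal mean ranks break toward +1
})

test_that("rank-sum p equals the exhaustive permutation oracle on small lists", {
  set.seed(16)
  for (i in 1:60) {
    N <- sample(3:10, 1); k <- sample(1:(N - 1), 1)
    ranks <- rank(sample(N), ties.method = "average")
    ## introduce ties in half the cases
    if (i %% 2 == 0) {
      v <- sample(1:ceiling(N / 2), N, replace = TRUE)
      ranks <- rank(v, ties.method = "average")
    }
    inR <- ranks[1:k]; outR <- ranks[-(1:k)]
    mine <- wilcoxonRank(inR, outR)
    orc <- oracleRankSum(inR, outR)
    expect_equal(mine$p, orc$p, tolerance = 1e-12)
    expect_equal(mine$pLower, orc$pLower, tolerance = 1e-12)
  }
})

test_that("rank-sum p is invariant under flipping the ranking direction", {
  set.seed(17)
  for (i in 1:20) {
    N <- sample(6:14, 1); k <- sample(2:(N - 2), 1)
    r <- sample(N)
    inR <- r[1:k]; outR <- r[-(1:k)]
    a <- wilcoxonRank(inR, outR)
    b <- wilcoxonRank(N + 1 - inR, N + 1 - outR)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    if (mean(inR) != mean(outR)) expect_equal(a$sign, -b$sign)
  }
})

test_that("normal approximation with tie/continuity correction tracks wilcox.test", {
  set.seed(18)
  for (i in 1:20) {
    N <- sample(20:40, 1); k <- sample(5:(N - 5), 1)
    v <- sample(1:15, N, replace = TRUE)   # heavy ties
    ranks <- rank(v, ties.method = "average")
    mine <- wilcoxonRank(ranks[1:k], ranks[-(1:k)], exactLimit = 12)
    ref <- suppressWarnings(
      wilcox.test(v[1:k], v[-(1:k)], exact = FALSE, correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})
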