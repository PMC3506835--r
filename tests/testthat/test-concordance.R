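mkDe2 <- function(gene_id, delta, p, contrast = "x") {
  data.frame(gene_id = gene_id, contrast = contrast, delta = delta,
             t_stat = delta, df = 4, p = p, q = p, stringsAsFactors = FALSE)
}

test_that("significant-intersection matches a filter-join oracle", {
  deA <- mkDe2(c("g1", "g2", "g3"), c(1, 2, 3), c(0.01, 0.2, 0.01))
  deB <- mkDe2(c("g1", "g2", "g3"), c(-1, 1, 2), c(0.04, 0.01, 0.2))
  got <- intersectSignificant(deA, deB, 0.05)
  expect_identical(got$gene_id, "g1")
  expect_equal(got$delta_invivo, 1)
  expect_equal(got$delta_invitro, -1)

  ## disjoint significance -> empty
  deC <- mkDe2(c("g1", "g2"), c(1, 1), c(0.01, 0.9))
  deD <- mkDe2(c("g1", "g2"), c(1, 1), c(0.9, 0.01))
  expect_equal(nrow(intersectSignificant(deC, deD)), 0)

  ## identical tables: everything, ordered by delta descending
  got2 <- intersectSignificant(deA, deA, 0.05)
  expect_identical(got2$gene_id, c("g3", "g1"))
  expect_equal(got2$delta_invivo, got2$delta_invitro)

  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    ids <- sprintf("g%03d", 1:n)
    dA <- mkDe2(ids, rnorm(n), runif(n))
    dB <- mkDe2(sample(ids), rnorm(n), runif(n))
    got3 <- intersectSignificant(dA, dB, 0.2)
    oracle <- intersect(dA$gene_id[dA$p < 0.2], dB$gene_id[dB$p < 0.2])
    expect_setequal(got3$gene_id, oracle)
  }
})

test_that("quadrant table uses strict signs and excludes exact zeros", {
  common <- data.frame(gene_id = paste0("g", 1:5),
                       delta_invivo = c(1, 2, -1, 0.5, 0),
                       delta_invitro = c(1, -1, 1, 2, 3))
  q <- quadrantContingency(common)
  expect_equal(unname(q$tab), matrix(c(2L, 1L, 1L, 0L), 2, byrow = TRUE))
  expect_equal(q$nExcludedZeroDelta, 1)

  allUp <- data.frame(gene_id = c("a", "b"), delta_invivo = c(1, 2),
                      delta_invitro = c(3, 4))
  expect_equal(unname(quadrantContingency(allUp)$tab),
               matrix(c(2L, 0L, 0L, 0L), 2))
  one <- data.frame(gene_id = "a", delta_invivo = 1, delta_invitro = -1)
  expect_equal(unname(quadrantContingency(one)$tab),
               matrix(c(0L, 1L, 0L, 0L), 2, byrow = TRUE))
  zero <- data.frame(gene_id = "a", delta_invivo = 0, delta_invitro = 1)
  expect_error(quadrantContingency(zero), "degenerate")

  set.seed(52)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    cm <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     delta_invivo = sample(c(-1, 1, 2, -0.5), n, TRUE),
                     delta_invitro = sample(c(-2, -1, 1, 3), n, TRUE))
    tab <- quadrantContingency(cm)$tab
    s1 <- sign(cm$delta_invivo); s2 <- sign(cm$delta_invitro)
    expect_equal(unname(tab),
                 matrix(c(sum(s1 > 0 & s2 > 0), sum(s1 > 0 & s2 < 0),
                          sum(s1 < 0 & s2 > 0), sum(s1 < 0 & s2 < 0)),
                        2, byrow = TRUE))
  }
})

test_that("prediction metrics are a/(a+b) and d/(c+d), missing when undefined", {
  tab <- matrix(c(9, 1, 0, 10), 2, byrow = TRUE)
  pm <- predictionMetrics(tab)
  expect_equal(pm$sensitivity, 0.9)
  expect_equal(pm$specificity, 1.0)
  pm2 <- predictionMetrics(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(is.na(pm2$sensitivity))
  expect_equal(pm2$specificity, 4 / 7)
  ## enumeration over all small tables
  for (n in 0:8) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    pm3 <- predictionMetrics(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    expect_equal(pm3$sensitivity,
                 if (a + b > 0) a / (a + b) else NA_real_)
    expect_equal(pm3$specificity,
                 if (cc + d > 0) d / (cc + d) else NA_real_)
  }
})

test_that("GO restriction subsets the common table exactly", {
  common <- data.frame(gene_id = c("g1", "g2", "g3"),
                       delta_invivo = 1:3, delta_invitro = 3:1)
  ann <- GOAnnotation(data.frame(gene_id = c("g1", "g3", "g9"),
                                 term_id = "t"),
                      data.frame(term_id = "t", term_name = "t",
                                 parent_ids = ""), expanded = TRUE)
  sub <- restrictToTerm(common, ann, "t")
  expect_setequal(sub$gene_id, c("g1", "g3"))
  expect_error(restrictToTerm(common, ann, "unknown"), "absent")
  annAll <- GOAnnotation(data.frame(gene_id = c("g1", "g2", "g3"),
                                    term_id = "t"),
                         data.frame(term_id = "t", term_name = "t",
                                    parent_ids = ""), expanded = TRUE)
  expect_identical(restrictToTerm(common, annAll, "t"), common)
})

test_that("concordance report wires counts, Fisher and correlation together", {
  set.seed(53)
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  base <- rnorm(n)
  deA <- mkDe2(ids, base + rnorm(n, 0, 0.3), runif(n, 0, 0.04))
  deB <- mkDe2(ids, base + rnorm(n, 0, 0.3), runif(n, 0, 0.04))
  rep <- concordanceAnalysis(deA, deB, 0.05)
  q <- quadrantTable(rep)
  expect_equal(rep@nCommon, sum(q) + rep@nExcludedZeroDelta)
  expect_equal(rep@nSameDirection, q[1, 1] + q[2, 2])
  expect_equal(rep@nBothUp, q[1, 1])
  expect_equal(rep@fisherP, fisherExact2x2(q), tolerance = 1e-12)
  cg <- commonGenes(rep)
  expect_equal(rep@r, pearsonR(cg$delta_invivo, cg$delta_invitro)$r,
               tolerance = 1e-12)
  expect_true(rep@r > 0.5)         # strongly shared effects by construction
  met <- concordanceMetrics(rep)
  expect_equal(met$n_both_up, rep@nBothUp)
})

test_that("attenuation analysis covers perfect reversal, no reversal and counting", {
  ids <- paste0("g", 1:6)
  deMS <- mkDe2(ids, c(2, 1, 0.5, -1, 3, 0.2),
                c(0.01, 0.01, 0.01, 0.01, 0.01, 0.5))
  deFM <- mkDe2(ids, -c(2, 1, 0.5, -1, 3, 0.2), rep(0.01, 6))
  att <- attenuationAnalysis(deMS, deFM, 0.05)
  expect_equal(att@nInduced, 4)             # g6 fails alpha, g4 not induced
  expect_equal(att@fractionReversed, 1)
  expect_equal(att@r, -1, tolerance = 1e-12)
  expect_equal(att@nFKSignificant, 6)

  deFM0 <- mkDe2(ids, rep(0, 6), rep(0.9, 6))
  att0 <- attenuationAnalysis(deMS, deFM0, 0.05)
  expect_equal(att0@fractionReversed, 0)
  expect_equal(att0@nFKSignificant, 0)

  deMSnone <- mkDe2(ids, -(1:6), rep(0.01, 6))
  attn <- attenuationAnalysis(deMSnone, deFM, 0.05)
  expect_equal(attn@nInduced, 0)
  expect_true(is.na(attn@fractionReversed))
  expect_error(attenuationAnalysis(deMS, deFM[-1, ], 0.05), "universe")
})

test_that("heatmap ordering sorts on the insult effect with lexicographic ties", {
  deMS <- mkDe2(c("g1", "g2", "g3"), c(0.5, 2, -1), rep(0.01, 3))
  got <- heatmapOrder(c("g1", "g2", "g3"), deMS)
  expect_identical(got$gene_id, c("g2", "g1", "g3"))

  deTie <- mkDe2(c("gb", "ga", "gc"), c(1, 1, 1), rep(0.01, 3))
  expect_identical(heatmapOrder(c("gb", "ga", "gc"), deTie)$gene_id,
                   c("ga", "gb", "gc"))
  expect_error(heatmapOrder("gX", deMS), "gX")

  deB <- mkDe2(c("g1", "g2", "g3"), c(1, 1, 1), c(0.01, 0.9, 0.01))
  flagged <- heatmapOrder(c("g1", "g2", "g3"), deMS, deB, 0.05)
  expect_identical(flagged$invitro_significant[match(c("g1", "g2", "g3"),
                                                     flagged$gene_id)],
                   c(TRUE, FALSE, TRUE))
})
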