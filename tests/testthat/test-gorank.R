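mkDe <- function(gene_id, delta, p) {
  data.frame(gene_id = gene_id, contrast = "M-S", delta = delta,
             t_stat = delta, df = 4, p = p, q = p, stringsAsFactors = FALSE)
}

simpleAnn <- function(pairs) {
  pairs <- unique(pairs)
  tids <- unique(pairs$term_id)
  GOAnnotation(pairs,
               data.frame(term_id = tids, term_name = tids, parent_ids = ""),
               expanded = TRUE)
}

test_that("gene ranking filters on alpha then orders by delta descending", {
  de <- mkDe(c("g1", "g2", "g3"), c(2, -1, 0.5), c(0.01, 0.02, 0.03))
  r <- rankGenes(de, 0.05)
  expect_identical(r$gene_id, c("g1", "g3", "g2"))
  expect_equal(r$rank, 1:3)
  expect_equal(nrow(rankGenes(de, 1e-12)), 0)

  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    de2 <- mkDe(sprintf("g%03d", 1:n), rnorm(n), runif(n))
    got <- rankGenes(de2, 0.3)
    keep <- de2[de2$p < 0.3, ]
    oracle <- keep$gene_id[order(-keep$delta, keep$gene_id)]
    expect_identical(got$gene_id, oracle)
  }
})

test_that("tied deltas receive average ranks", {
  de <- mkDe(c("g1", "g2", "g3", "g4"), c(2, 1, 1, 0), rep(0.01, 4))
  r <- rankGenes(de)
  expect_equal(r$rank, c(1, 2.5, 2.5, 4))
})

test_that("association of a top-loaded term is extreme, positive, exact", {
  de <- mkDe(paste0("g", 1:5), c(5, 4, 3, 2, 1), rep(0.01, 5))
  ranked <- rankGenes(de)
  ann <- simpleAnn(data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                              term_id = c("top", "top", "bg", "bg", "bg")))
  got <- goAssociations(ranked, ann)
  top <- got[got$term_id == "top", ]
  expect_equal(top$sign, 1)
  expect_equal(top$p, 0.2)                     # two-sided of the 0.1 tail
  expect_equal(wilcoxonRank(c(1, 2), c(3, 4, 5))$pLower, 0.1)
  expect_equal(top$n_genes, 2)
})

test_that("a term covering the whole list is not testable", {
  de <- mkDe(paste0("g", 1:6), 6:1, rep(0.01, 6))
  ann <- simpleAnn(data.frame(gene_id = paste0("g", 1:6), term_id = "all"))
  got <- goAssociations(rankGenes(de), ann)
  expect_false("all" %in% got$term_id)
})

test_that("reversing the ranking flips every sign and keeps every |score|", {
  set.seed(42)
  n <- 30
  de <- mkDe(sprintf("g%03d", 1:n), rnorm(n), runif(n, 0, 0.04))
  pairs <- data.frame(gene_id = sprintf("g%03d", sample(n, 40, TRUE)),
                      term_id = paste0("t", sample(1:4, 40, TRUE)))
  ann <- simpleAnn(unique(pairs))
  fwd <- goAssociations(rankGenes(de), ann)
  deRev <- de; deRev$delta <- -de$delta
  rev <- goAssociations(rankGenes(deRev), ann)
  rev <- rev[match(fwd$term_id, rev$term_id), ]
  expect_equal(rev$sign, -fwd$sign)
  expect_equal(abs(rev$signed_score), abs(fwd$signed_score), tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("association p-values ignore the order of genes with tied deltas", {
  de <- mkDe(paste0("g", 1:6), c(3, 1, 1, 1, 0.5, -1), rep(0.01, 6))
  ann <- simpleAnn(data.frame(gene_id = c("g2", "g4"), term_id = "t"))
  p1 <- goAssociations(rankGenes(de), ann)$p
  ## permute the tied block by renaming: g2 <-> g3 swap membership
  ann2 <- simpleAnn(data.frame(gene_id = c("g3", "g4"), term_id = "t"))
  p2 <- goAssociations(rankGenes(de), ann2)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("signed_score is zero iff p_fdr is one", {
  set.seed(43)
  n <- 20
  de <- mkDe(sprintf("g%03d", 1:n), rnorm(n), runif(n, 0, 0.04))
  ann <- simpleAnn(data.frame(gene_id = sprintf("g%03d", sample(n, 30, TRUE)),
                              term_id = paste0("t", sample(1:5, 30, TRUE))))
  got <- goAssociations(rankGenes(de), ann)
  expect_identical(got$signed_score == 0, got$p_fdr == 1)
  expect_equal(abs(got$signed_score), -log10(got$p_fdr), tolerance = 1e-12)
})

test_that("Venn region counts partition the annotated subset", {
  pairs <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3", "g4"),
    term_id = c("A", "B", "A", "A", "B", "C", "D"))
  ann <- simpleAnn(pairs)
  got <- termMembershipCounts(c("g1", "g2", "g3", "g5"), ann, c("A", "B", "C"))
  expect_equal(got$perTerm$n, c(3, 2, 1))
  expect_equal(sum(got$regions$n), attr(got$regions, "n_annotated"))
  expect_equal(attr(got$regions, "n_annotated"), 3)  # g5 unannotated
  expect_equal(got$regions$n[got$regions$mask == "111"], 1)  # g3

  ## identical membership of two terms -> only the intersection region
  ann2 <- simpleAnn(data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                               term_id = c("A", "B", "A", "B")))
  got2 <- termMembershipCounts(c("g1", "g2"), ann2, c("A", "B"))
  expect_identical(got2$regions$mask, "11")
  expect_equal(got2$regions$n, 2)

  ## no annotated gene -> zero regions
  got3 <- termMembershipCounts("g9", ann, c("A", "B"))
  expect_equal(nrow(got3$regions), 0)
  expect_error(termMembershipCounts("g1", ann, c("A", "nope")), "nope")
})

test_that("Venn regions match a brute-force assignment on random sets", {
  set.seed(44)
  for (i in 1:10) {
    genes <- sprintf("g%02d", 1:25)
    pairs <- data.frame(gene_id = sample(genes, 60, TRUE),
                        term_id = sample(c("A", "B", "C", "D"), 60, TRUE))
    ann <- simpleAnn(unique(pairs))
    gs <- sample(genes, 15)
    got <- termMembershipCounts(gs, ann, c("A", "B", "C", "D"))
    oracle <- table(vapply(gs, function(g) {
      m <- vapply(c("A", "B", "C", "D"),
                  function(t) g %in% genesForTerm(ann, t), TRUE)
      if (!any(m)) "" else paste(as.integer(m), collapse = "")
    }, ""))
    oracle <- oracle[names(oracle) != ""]
    expect_equal(sort(got$regions$n), sort(as.integer(oracle)))
  }
})
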