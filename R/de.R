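#' Per-gene Welch contrast on a gene matrix
#'
#' Runs the Welch t-test gene-wise between two conditions of one
#' experiment and assembles a differential table. The log2 change is
#' oriented \code{groupB - groupA} and the contrast is labelled
#' \code{"<groupB>-<groupA>"} (e.g. \code{"M-S"}).
#'
#' @param ge a \linkS4class{GeneExperiment}.
#' @param design validated study design covering the samples of \code{ge}.
#' @param groupA,groupB condition labels (reference first).
#' @return data.frame with columns gene_id, contrast, delta, t_stat, df,
#'   p, q, sorted by p ascending (ties by gene_id). q are Storey q-values;
#'   the pi0 estimate is attached as attribute \code{"pi0"}.
#' @export
runWelchContrast <- function(ge, design, groupA, groupB) {
  m <- log2expr(ge)
  design <- validateDesign(design)
  idxA <- contrastIdx(m, design, groupA)
  idxB <- contrastIdx(m, design, groupB)
  r <- welchRows(m[, idxA, drop = FALSE], m[, idxB, drop = FALSE])
  deTable(rownames(m), paste0(groupB, "-", groupA), r$delta, r$t, r$df, r$p)
}

contrastIdx <- function(m, design, group) {
  ids <- design$sample_id[design$condition == group]
  idx <- which(colnames(m) %in% ids)
  if (length(idx) < 2)
    stopFmt("condition '", group, "' has fewer than 2 samples in the matrix")
  idx
}

#' Per-gene paired contrast
#'
#' Paired t-test gene-wise over matched sample pairs (e.g. control/LPS
#' preparations). Pairs are taken from the design's \code{pair_id};
#' unpaired samples are excluded from the test and logged. The per-pair
#' difference is oriented \code{groupB - groupA}.
#'
#' @inheritParams runWelchContrast
#' @return differential table as in [runWelchContrast()], with df = number
#'   of pairs - 1.
#' @export
runPairedContrast <- function(ge, design, groupA, groupB) {
  m <- log2expr(ge)
  design <- validateDesign(design)
  d <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  paired <- d[!is.na(d$pair_id), , drop = FALSE]
  nUnpaired <- nrow(d) - nrow(paired)
  if (nUnpaired > 0)
    xcLog(nUnpaired, " unpaired sample(s) excluded from the paired test")
  pids <- unique(paired$pair_id)
  sA <- sB <- character(0)
  for (pid in pids) {
    grp <- paired[paired$pair_id == pid, , drop = FALSE]
    a <- grp$sample_id[grp$condition == groupA]
    b <- grp$sample_id[grp$condition == groupB]
    if (length(a) == 1 && length(b) == 1) {
      sA <- c(sA, a); sB <- c(sB, b)
    }
  }
  if (length(sA) < 2) stopFmt("fewer than 2 complete pairs for ",
                              groupB, "-", groupA)
  diffs <- m[, sB, drop = FALSE] - m[, sA, drop = FALSE]
  r <- pairedRows(diffs)
  deTable(rownames(m), paste0(groupB, "-", groupA), r$delta, r$t, r$df, r$p)
}

#' Per-gene one-way ANOVA screen
#'
#' Classical one-way F test gene-wise across all conditions of one
#' experiment (e.g. the three-condition S/M/F screen). The \code{delta}
#' column is NA: the screen has no single contrast orientation.
#'
#' @inheritParams runWelchContrast
#' @param conditions condition labels to include (default: all in the
#'   design).
#' @return differential table with t_stat holding the F statistic and df
#'   the denominator degrees of freedom.
#' @export
runAnovaScreen <- function(ge, design, conditions = NULL) {
  m <- log2expr(ge)
  design <- validateDesign(design)
  d <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  if (!is.null(conditions)) d <- d[d$condition %in% conditions, , drop = FALSE]
  tab <- table(d$condition)
  if (length(tab) < 2) stopFmt("ANOVA screen needs >= 2 conditions")
  if (any(tab < 2)) stopFmt("every condition needs >= 2 samples")
  m <- m[, d$sample_id, drop = FALSE]
  r <- anovaRows(m, d$condition)
  deTable(rownames(m), paste(names(tab), collapse = "/"),
          rep(NA_real_, nrow(m)), r$F, rep(r$df2, nrow(m)), r$p)
}

deTable <- function(geneIds, contrast, delta, stat, df, p) {
  q <- storeyQvalues(p)
  out <- data.frame(gene_id = geneIds, contrast = contrast, delta = delta,
                    t_stat = stat, df = df, p = p, q = q$q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pi0") <- q$pi0
  out
}
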