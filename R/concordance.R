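#' Genes significant in both systems
#'
#' Intersects two differential tables at p < alpha and carries both log2
#' changes, ordered by the first system's delta descending.
#'
#' @param deA,deB differential tables over a shared gene identifier space
#'   (A = in vivo, B = in vitro by convention).
#' @param alpha significance threshold applied to both tables.
#' @return data.frame gene_id, delta_invivo, delta_invitro. Empty
#'   intersection is allowed (logged).
#' @export
intersectSignificant <- function(deA, deB, alpha = 0.05) {
  sigA <- deA[deA$p < alpha, c("gene_id", "delta")]
  sigB <- deB[deB$p < alpha, c("gene_id", "delta")]
  common <- merge(sigA, sigB, by = "gene_id", suffixes = c("_invivo", "_invitro"))
  names(common) <- c("gene_id", "delta_invivo", "delta_invitro")
  common <- common[order(-common$delta_invivo, common$gene_id), , drop = FALSE]
  rownames(common) <- NULL
  if (nrow(common) == 0) xcLog("no gene significant in both systems")
  common
}

#' Quadrant contingency table of cross-system signs
#'
#' Classifies the common genes by the sign of their log2 change in each
#' system: rows in vivo up/down, columns in vitro up/down, strict
#' inequalities. Genes with a log2 change of exactly 0 in either system
#' carry no sign and are excluded (counted).
#'
#' @param common common-gene table from [intersectSignificant()].
#' @return list with \code{tab} (2x2 integer matrix) and
#'   \code{nExcludedZeroDelta}.
#' @export
quadrantContingency <- function(common) {
  if (nrow(common) == 0) stopFmt("common table is empty")
  zero <- common$delta_invivo == 0 | common$delta_invitro == 0
  if (all(zero)) stopFmt("degenerate: all common genes have a zero delta")
  cc <- common[!zero, , drop = FALSE]
  up1 <- cc$delta_invivo > 0
  up2 <- cc$delta_invitro > 0
  tab <- matrix(c(sum(up1 & up2), sum(up1 & !up2),
                  sum(!up1 & up2), sum(!up1 & !up2)),
                nrow = 2, byrow = TRUE,
                dimnames = list(invivo = c("up", "down"),
                                invitro = c("up", "down")))
  storage.mode(tab) <- "integer"
  list(tab = tab, nExcludedZeroDelta = sum(zero))
}

#' Prediction sensitivity and specificity from a quadrant table
#'
#' Treats in vitro induction as a classifier for in vivo induction among
#' the common genes: sensitivity = a/(a+b), specificity = d/(c+d) with the
#' quadrant table (a, b // c, d). An empty denominator yields NA (the
#' metric is missing, never 0).
#'
#' @param tab 2x2 matrix (rows in vivo up/down, cols in vitro up/down).
#' @return list with \code{sensitivity} and \code{specificity}.
#' @export
predictionMetrics <- function(tab) {
  stopifnot(is.matrix(tab), identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  list(sensitivity = if (a + b > 0) a / (a + b) else NA_real_,
       specificity = if (c + d > 0) d / (c + d) else NA_real_)
}

#' Restrict a common-gene table to one GO term
#'
#' @param common common-gene table from [intersectSignificant()].
#' @param annotation an expanded \linkS4class{GOAnnotation}.
#' @param termId GO term to restrict to; must exist in the annotation.
#' @return the subset of \code{common} annotated to the term (possibly
#'   empty).
#' @export
restrictToTerm <- function(common, annotation, termId) {
  genes <- genesForTerm(annotation, termId)
  out <- common[common$gene_id %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full cross-system concordance analysis
#'
#' Intersects two differential tables, computes the Pearson correlation of
#' the two systems' log2 changes over the common genes, the quadrant
#' contingency table, the two-sided Fisher association p-value of
#' same-direction regulation, and the sensitivity/specificity of
#' predicting in vivo induction from in vitro induction. Optionally the
#' whole analysis is repeated on the subset annotated to one GO term.
#'
#' @inheritParams intersectSignificant
#' @param annotation optional expanded \linkS4class{GOAnnotation}, required
#'   when \code{restrictTerm} is given.
#' @param restrictTerm optional term id for the restricted re-analysis.
#' @return a \linkS4class{ConcordanceReport}.
#' @export
concordanceAnalysis <- function(deA, deB, alpha = 0.05, annotation = NULL,
                                restrictTerm = NULL) {
  common <- intersectSignificant(deA, deB, alpha)
  rep <- concordanceFromCommon(common)
  if (!is.null(restrictTerm)) {
    if (is.null(annotation))
      stopFmt("restriction requires an annotation")
    sub <- restrictToTerm(common, annotation, restrictTerm)
    rep@restrictedTerm <- restrictTerm
    if (nrow(sub) > 0) rep@restricted <- list(concordanceFromCommon(sub))
    else xcLog("no common gene annotated to ", restrictTerm)
  }
  rep
}

concordanceFromCommon <- function(common) {
  if (nrow(common) == 0) {
    return(new("ConcordanceReport", common = common,
               quadrant = matrix(0L, 2, 2), nCommon = 0L,
               nSameDirection = 0L, nBothUp = 0L,
               nExcludedZeroDelta = 0L, r = NA_real_, rP = NA_real_,
               fisherP = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, restrictedTerm = NA_character_,
               restricted = list()))
  }
  q <- quadrantContingency(common)
  tab <- q$tab
  pm <- predictionMetrics(tab)
  rr <- if (nrow(common) >= 3 &&
            stats::sd(common$delta_invivo) > 0 &&
            stats::sd(common$delta_invitro) > 0)
    pearsonR(common$delta_invivo, common$delta_invitro)
  else list(r = NA_real_, p = NA_real_)
  common$quadrant <- quadrantLabel(common)
  new("ConcordanceReport", common = common, quadrant = tab,
      nCommon = nrow(common),
      nSameDirection = tab[1, 1] + tab[2, 2],
      nBothUp = tab[1, 1],
      nExcludedZeroDelta = as.integer(q$nExcludedZeroDelta),
      r = rr$r, rP = rr$p, fisherP = fisherExact2x2(tab),
      sensitivity = pm$sensitivity, specificity = pm$specificity,
      restrictedTerm = NA_character_, restricted = list())
}

quadrantLabel <- function(common) {
  ifelse(common$delta_invivo == 0 | common$delta_invitro == 0, "excluded",
  ifelse(common$delta_invivo > 0,
         ifelse(common$delta_invitro > 0, "I", "II"),
         ifelse(common$delta_invitro > 0, "IV", "III")))
}

#' Drug-attenuation analysis
#'
#' Quantifies how far the drug pushes back insult-induced expression
#' changes: among genes significantly induced by the insult
#' (\code{p < alpha} and \code{delta_MS > 0} in the M-S table), the
#' fraction whose drug contrast (F-M) is negative, plus the correlation
#' between the two contrasts' log2 changes over all insult-significant
#' genes, and the number of genes significant for the drug contrast
#' itself.
#'
#' @param deMS differential table of the insult contrast (M-S).
#' @param deFM differential table of the drug contrast (F-M), same gene
#'   universe.
#' @param alpha significance threshold.
#' @return an \linkS4class{AttenuationReport}.
#' @export
attenuationAnalysis <- function(deMS, deFM, alpha = 0.05) {
  if (!setequal(deMS$gene_id, deFM$gene_id))
    stopFmt("the two tables must cover the same gene universe")
  sig <- deMS[deMS$p < alpha, , drop = FALSE]
  tabl <- data.frame(gene_id = sig$gene_id, delta_MS = sig$delta,
                     delta_FM = deFM$delta[match(sig$gene_id, deFM$gene_id)],
                     stringsAsFactors = FALSE)
  tabl$induced <- tabl$delta_MS > 0
  tabl$reversed <- tabl$induced & tabl$delta_FM < 0
  nInd <- sum(tabl$induced)
  nRev <- sum(tabl$reversed)
  if (nInd == 0) xcLog("no insult-induced gene at alpha = ", alpha)
  r <- if (nrow(tabl) >= 3 && stats::sd(tabl$delta_MS) > 0 &&
           stats::sd(tabl$delta_FM) > 0)
    pearsonR(tabl$delta_MS, tabl$delta_FM)$r else NA_real_
  new("AttenuationReport", table = tabl,
      nInduced = as.integer(nInd), nInducedReversed = as.integer(nRev),
      nFKSignificant = as.integer(sum(deFM$p < alpha)),
      fractionReversed = if (nInd > 0) nRev / nInd else NA_real_,
      r = r)
}

#' Heatmap gene ordering
#'
#' Orders a gene set by the insult-induced log2 change (M-S) descending,
#' ties broken by gene id, and flags each gene that is also significant in
#' the in vitro contrast — the plot-ready row order for an expression
#' heatmap.
#'
#' @param geneSet character vector of gene ids; every one must occur in
#'   \code{deMS}.
#' @param deMS differential table of the insult contrast.
#' @param deInvitro optional in vitro differential table used for the
#'   significance flag.
#' @param alpha threshold for the flag.
#' @return data.frame gene_id, delta_MS, invitro_significant in heatmap
#'   order.
#' @export
heatmapOrder <- function(geneSet, deMS, deInvitro = NULL, alpha = 0.05) {
  miss <- setdiff(geneSet, deMS$gene_id)
  if (length(miss)) stopFmt("gene '", miss[1], "' missing from the M-S table")
  d <- deMS[match(geneSet, deMS$gene_id), c("gene_id", "delta")]
  names(d)[2] <- "delta_MS"
  d$invitro_significant <- if (is.null(deInvitro)) NA else
    d$gene_id %in% deInvitro$gene_id[deInvitro$p < alpha]
  d <- d[order(-d$delta_MS, d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}
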