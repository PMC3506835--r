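#' Rank significant genes on their log2 change
#'
#' Keeps the genes with p < alpha and orders them by log2 change,
#' largest increase first — the ranked input of the rank-based GO
#' association. Ties in delta receive average ranks downstream.
#'
#' @param de differential table (see [runWelchContrast()]).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame gene_id, delta, rank (average ranks for tied
#'   deltas); zero rows when nothing passes alpha (logged).
#' @export
rankGenes <- function(de, alpha = 0.05) {
  keep <- de[de$p < alpha, , drop = FALSE]
  if (nrow(keep) == 0) {
    xcLog("no gene passes alpha = ", alpha, "; ranked list is empty")
    return(data.frame(gene_id = character(0), delta = numeric(0),
                      rank = numeric(0)))
  }
  keep <- keep[order(-keep$delta, keep$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = keep$gene_id, delta = keep$delta,
                    rank = rank(-keep$delta, ties.method = "average"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-based GO association with signed log10 scores
#'
#' For every annotation term whose membership within the ranked list falls
#' inside the size bounds, compares the in-term ranks against the
#' out-of-term ranks ([wilcoxonRank()]), adjusts the p-values across all
#' tested terms by Benjamini-Hochberg, and reports the signed score
#' \code{sign * -log10(p_fdr)}: positive when the term's genes sit toward
#' the increased-expression end of the ranking, negative toward the
#' decreased end.
#'
#' @param ranked ranked gene list from [rankGenes()].
#' @param annotation an expanded \linkS4class{GOAnnotation}.
#' @param minSize,maxSize term-size bounds within the list; defaults 2 and
#'   list size - 2 so both rank groups have at least two members.
#' @return data.frame term_id, term_name, n_genes, p, p_fdr, sign,
#'   signed_score, sorted by signed_score descending. Zero rows when no
#'   term is testable (logged).
#' @export
goAssociations <- function(ranked, annotation, minSize = 2, maxSize = NULL) {
  if (nrow(ranked) == 0) stopFmt("ranked list is empty")
  if (!isExpanded(annotation))
    xcLog("annotation is not ancestor-expanded; using it as-is")
  if (is.null(maxSize) || is.na(maxSize)) maxSize <- nrow(ranked) - 2
  pairs <- annotationPairs(annotation)
  pairs <- pairs[pairs$gene_id %in% ranked$gene_id, , drop = FALSE]
  terms <- termTable(annotation)
  byTerm <- split(pairs$gene_id, pairs$term_id)
  sizes <- lengths(byTerm)
  testable <- names(byTerm)[sizes >= minSize & sizes <= maxSize]
  if (!length(testable)) {
    xcLog("no testable term within size bounds [", minSize, ", ", maxSize, "]")
    return(data.frame(term_id = character(0), term_name = character(0),
                      n_genes = integer(0), p = numeric(0),
                      p_fdr = numeric(0), sign = integer(0),
                      signed_score = numeric(0)))
  }
  rks <- ranked$rank
  names(rks) <- ranked$gene_id
  res <- lapply(testable, function(t) {
    inG <- ranked$gene_id %in% byTerm[[t]]
    w <- wilcoxonRank(rks[inG], rks[!inG])
    data.frame(term_id = t, n_genes = sum(inG), p = w$p, sign = w$sign,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- bhAdjust(res$p)
  capped <- res$p_fdr < 1e-300
  if (any(capped)) xcLog(sum(capped), " p_fdr value(s) capped at 1e-300")
  res$signed_score <- res$sign * -log10(pmax(res$p_fdr, 1e-300))
  res$term_name <- terms$term_name[match(res$term_id, terms$term_id)]
  res$term_name[is.na(res$term_name)] <- res$term_id[is.na(res$term_name)]
  res <- res[order(-res$signed_score, res$term_id),
             c("term_id", "term_name", "n_genes", "p", "p_fdr",
               "sign", "signed_score")]
  rownames(res) <- NULL
  res
}

#' Per-term and Venn-region membership counts
#'
#' Counts how many genes of a set are annotated to each of up to four
#' configured terms, and to every intersection region of those terms (the
#' regions partition the annotated subset of the gene set) — the
#' plot-ready table for a Venn diagram.
#'
#' @param geneSet character vector of gene ids.
#' @param annotation an expanded \linkS4class{GOAnnotation}.
#' @param termIds configured term ids (<= 4); every one must occur in the
#'   annotation's term table.
#' @return list with \code{perTerm} (data.frame term_id, n) and
#'   \code{regions} (data.frame mask — e.g. "1011" over the term order —
#'   terms, n; only nonempty regions, plus attribute
#'   \code{"n_annotated"}).
#' @export
termMembershipCounts <- function(geneSet, annotation, termIds) {
  if (length(termIds) < 1 || length(termIds) > 4)
    stopFmt("between 1 and 4 terms of interest required")
  known <- unique(c(termTable(annotation)$term_id,
                    annotationPairs(annotation)$term_id))
  miss <- setdiff(termIds, known)
  if (length(miss)) stopFmt("term '", miss[1], "' absent from annotation")
  geneSet <- unique(geneSet)
  member <- vapply(termIds, function(t)
    geneSet %in% genesForTerm(annotation, t), logical(length(geneSet)))
  member <- matrix(member, nrow = length(geneSet),
                   dimnames = list(geneSet, termIds))
  perTerm <- data.frame(term_id = termIds, n = colSums(member),
                        row.names = NULL, stringsAsFactors = FALSE)
  annotated <- rowSums(member) > 0
  masks <- apply(member[annotated, , drop = FALSE], 1,
                 function(z) paste(as.integer(z), collapse = ""))
  tab <- table(masks)
  regions <- data.frame(mask = names(tab),
                        terms = vapply(names(tab), function(mk) {
                          paste(termIds[strsplit(mk, "")[[1]] == "1"],
                                collapse = "&")
                        }, ""),
                        n = as.integer(tab), row.names = NULL,
                        stringsAsFactors = FALSE)
  attr(regions, "n_annotated") <- sum(annotated)
  list(perTerm = perTerm, regions = regions)
}
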