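#' Detection-call filtering
#'
#' Retains exactly the probesets that are consistently detected — call
#' \code{P} (Present) or \code{M} (Marginal) in every sample — in at least
#' one condition of the design. Sample columns and probeset order are
#' preserved. An empty result is not an error; it is returned (and logged)
#' as a 0-row experiment.
#'
#' @param pe a \linkS4class{ProbesetExperiment}.
#' @param design a validated study design covering every sample of
#'   \code{pe} (see [validateDesign()]).
#' @return the filtered \linkS4class{ProbesetExperiment}.
#' @export
filterDetected <- function(pe, design) {
  design <- validateDesign(design)
  miss <- setdiff(colnames(pe), design$sample_id)
  if (length(miss))
    stopFmt("samples absent from design: ", paste(miss, collapse = ", "))
  cond <- design$condition[match(colnames(pe), design$sample_id)]
  cl <- calls(pe)
  detected <- cl == "P" | cl == "M"
  keep <- rep(FALSE, nrow(pe))
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    keep <- keep | rowSums(detected[, idx, drop = FALSE]) == length(idx)
  }
  xcLog(sum(keep), " of ", nrow(pe), " probesets consistently detected ",
        "in at least one condition")
  pe[keep, ]
}

#' Collapse probesets to gene-level log2 expression
#'
#' For every gene with at least one retained mapped probeset, the
#' per-sample gene value is \code{log2(mean(linear intensities of its
#' probesets))}: averaging is done on the linear scale first, then the
#' average profile is log2-transformed. Probesets absent from the mapping
#' are dropped (and counted in the log).
#'
#' @param pe a filtered \linkS4class{ProbesetExperiment} with positive
#'   intensities for retained cells.
#' @param map probeset-to-gene mapping (see [readGeneMap()]).
#' @return a \linkS4class{GeneExperiment}, genes ordered by gene_id.
#' @export
collapseToGenes <- function(pe, map) {
  map <- validateGeneMap(map)
  x <- intensities(pe)
  hit <- rownames(x) %in% map$probeset_id
  if (sum(!hit))
    xcLog(sum(!hit), " unmapped probesets dropped at gene collapsing")
  x <- x[hit, , drop = FALSE]
  if (nrow(x) == 0) stopFmt("no mapped probesets to collapse")
  gene <- map$gene_id[match(rownames(x), map$probeset_id)]
  sums <- rowsum(x, gene)
  avg <- sums / as.vector(table(gene)[rownames(sums)])
  bad <- which(avg <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopFmt("averaged intensity <= 0 for gene '", rownames(avg)[bad[1, 1]],
            "', sample '", colnames(avg)[bad[1, 2]], "'")
  m <- log2(avg)
  xcLog(nrow(m), " genes formed from ", nrow(x), " mapped probesets")
  new("GeneExperiment", SummarizedExperiment(assays = list(log2expr = m)))
}

#' Per-experiment preprocessing
#'
#' Convenience wrapper applying [filterDetected()] then [collapseToGenes()]
#' for one experiment, returning both the gene matrix and a filter report.
#'
#' @inheritParams filterDetected
#' @inheritParams collapseToGenes
#' @return list with elements \code{genes} (a
#'   \linkS4class{GeneExperiment}) and \code{report} (data.frame with
#'   probesets in/out and genes formed).
#' @export
preprocessExperiment <- function(pe, design, map) {
  filt <- filterDetected(pe, design)
  ge <- collapseToGenes(filt, map)
  report <- data.frame(probesets_in = nrow(pe),
                       probesets_detected = nrow(filt),
                       genes_formed = nrow(ge))
  list(genes = ge, report = report)
}
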