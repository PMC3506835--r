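#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<- rowData
NULL

VALID_CALLS <- c("P", "M", "A")

#' Probeset-level experiment container
#'
#' Holds linear-scale probeset intensities together with their per-cell
#' detection calls (Present / Marginal / Absent) as two assays of a
#' \linkS4class{SummarizedExperiment}. Sample annotation (experiment label,
#' condition, optional pair identifier) lives in \code{colData}.
#'
#' Validity requires: finite, non-negative intensities; calls in
#' \code{{"P","M","A"}}; identical dimensions and dimnames for the two
#' assays; unique probeset and sample identifiers.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure with assays
#'   \code{intensity} (numeric) and \code{call} (character).
#' @seealso [ProbesetExperiment()], [filterDetected()], [collapseToGenes()]
#' @export
setClass("ProbesetExperiment", contains = "SummarizedExperiment")

setValidity("ProbesetExperiment", function(object) {
  msg <- character(0)
  if (!all(c("intensity", "call") %in% assayNames(object)))
    return("assays 'intensity' and 'call' are both required")
  x <- assay(object, "intensity")
  cl <- assay(object, "call")
  if (!is.numeric(x)) msg <- c(msg, "intensity assay must be numeric")
  else {
    if (any(!is.finite(x))) msg <- c(msg, "intensity values must be finite")
    if (any(x < 0, na.rm = TRUE)) msg <- c(msg, "intensity values must be >= 0")
  }
  if (!all(cl %in% VALID_CALLS))
    msg <- c(msg, "detection calls must be one of 'P', 'M', 'A'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probeset_id")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample_id")
  if (length(msg)) msg else TRUE
})

#' Construct a ProbesetExperiment
#'
#' @param intensity numeric matrix of linear-scale intensities, probesets x
#'   samples, with probeset ids as rownames and sample ids as colnames.
#' @param call character matrix of detection calls (\code{"P"}, \code{"M"},
#'   \code{"A"}) with the same shape and dimnames as \code{intensity}.
#' @param design optional study design \code{data.frame}
#'   (see [readDesign()]); when supplied, its rows are matched to the
#'   columns and stored in \code{colData}.
#' @return a \linkS4class{ProbesetExperiment}.
#' @examples
#' x <- matrix(c(100, 50, 200, 80), 2, 2,
#'             dimnames = list(c("ps1", "ps2"), c("s1", "s2")))
#' calls <- matrix(c("P", "A", "P", "M"), 2, 2, dimnames = dimnames(x))
#' ProbesetExperiment(x, calls)
#' @export
ProbesetExperiment <- function(intensity, call, design = NULL) {
  if (!identical(dim(intensity), dim(call)))
    stop("intensity and call matrices differ in shape: ",
         paste(dim(intensity), collapse = "x"), " vs ",
         paste(dim(call), collapse = "x"))
  if (!identical(dimnames(intensity), dimnames(call))) {
    bad <- firstLabelMismatch(dimnames(intensity), dimnames(call))
    stop("intensity and call matrices disagree on label '", bad, "'")
  }
  se <- SummarizedExperiment(assays = list(intensity = intensity, call = call))
  if (!is.null(design)) {
    design <- validateDesign(design)
    miss <- setdiff(colnames(se), design$sample_id)
    if (length(miss))
      stop("samples absent from design: ", paste(miss, collapse = ", "))
    cd <- design[match(colnames(se), design$sample_id), , drop = FALSE]
    colData(se) <- DataFrame(cd, row.names = colnames(se))
  }
  new("ProbesetExperiment", se)
}

firstLabelMismatch <- function(a, b) {
  for (i in seq_along(a)) {
    d <- c(setdiff(a[[i]], b[[i]]), setdiff(b[[i]], a[[i]]))
    if (length(d)) return(d[1])
  }
  "<unknown>"
}

#' Gene-level log2 expression container
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{log2expr}
#' holding gene-level log2-scale expression after probeset averaging
#' (see [collapseToGenes()]). All values must be finite and gene ids unique.
#'
#' @seealso [collapseToGenes()], [runContrast()]
#' @export
setClass("GeneExperiment", contains = "SummarizedExperiment")

setValidity("GeneExperiment", function(object) {
  msg <- character(0)
  if (!("log2expr" %in% assayNames(object)))
    return("assay 'log2expr' is required")
  x <- assay(object, "log2expr")
  if (!is.numeric(x) || any(!is.finite(x)))
    msg <- c(msg, "log2expr must be finite numeric")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated gene_id")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated sample_id")
  if (length(msg)) msg else TRUE
})

#' Gene Ontology annotation with parent relation
#'
#' Stores gene-to-term memberships plus a term table carrying display names
#' and the parent relation, from which ancestor expansion is computed
#' (see [expandAnnotation()]). The \code{expanded} flag records whether the
#' membership is closed under the parent relation.
#'
#' @slot pairs data.frame with columns \code{gene_id}, \code{term_id};
#'   unique rows.
#' @slot terms data.frame with columns \code{term_id}, \code{term_name},
#'   \code{parent_ids} (comma-joined, possibly empty).
#' @slot expanded logical scalar.
#' @export
setClass("GOAnnotation",
         representation(pairs = "data.frame", terms = "data.frame",
                        expanded = "logical"),
         prototype(pairs = data.frame(gene_id = character(0),
                                      term_id = character(0)),
                   terms = data.frame(term_id = character(0),
                                      term_name = character(0),
                                      parent_ids = character(0)),
                   expanded = FALSE))

setValidity("GOAnnotation", function(object) {
  msg <- character(0)
  if (!all(c("gene_id", "term_id") %in% colnames(object@pairs)))
    msg <- c(msg, "pairs needs columns gene_id, term_id")
  if (!all(c("term_id", "term_name", "parent_ids") %in% colnames(object@terms)))
    msg <- c(msg, "terms needs columns term_id, term_name, parent_ids")
  if (anyDuplicated(object@terms$term_id))
    msg <- c(msg, "duplicated term_id in term table")
  if (isTRUE(object@expanded) &&
      anyDuplicated(object@pairs[c("gene_id", "term_id")]))
    msg <- c(msg, "expanded annotation must have unique gene-term pairs")
  if (length(msg)) msg else TRUE
})

#' Construct a GOAnnotation
#'
#' @param pairs data.frame with columns \code{gene_id}, \code{term_id}.
#' @param terms data.frame with columns \code{term_id}, \code{term_name},
#'   \code{parent_ids} (comma-joined parent term ids, may be empty strings).
#' @param expanded logical; set by [expandAnnotation()], rarely by hand.
#' @return a \linkS4class{GOAnnotation}.
#' @export
GOAnnotation <- function(pairs, terms, expanded = FALSE) {
  pairs <- data.frame(gene_id = as.character(pairs$gene_id),
                      term_id = as.character(pairs$term_id),
                      stringsAsFactors = FALSE)
  terms <- data.frame(term_id = as.character(terms$term_id),
                      term_name = as.character(terms$term_name),
                      parent_ids = as.character(terms$parent_ids),
                      stringsAsFactors = FALSE)
  new("GOAnnotation", pairs = pairs, terms = terms, expanded = expanded)
}

setMethod("show", "GOAnnotation", function(object) {
  cat(class(object), "with", nrow(object@pairs), "gene-term pairs over",
      nrow(object@terms), "terms",
      if (object@expanded) "(ancestor-expanded)\n" else "(raw)\n")
})

#' Cross-system concordance report
#'
#' Result container of [concordanceAnalysis()]: the common-gene table, the
#' quadrant contingency table, correlation of the two systems' log2 changes,
#' Fisher association p-value, and the prediction sensitivity/specificity of
#' in vitro induction for in vivo induction. A GO-restricted re-analysis may
#' be attached in \code{restricted}.
#'
#' @slot common data.frame: gene_id, delta_invivo, delta_invitro, quadrant.
#' @slot quadrant 2x2 integer matrix (rows: in vivo up/down, cols: in vitro
#'   up/down).
#' @slot nCommon,nSameDirection,nBothUp,nExcludedZeroDelta integer scalars.
#' @slot r,rP,fisherP numeric scalars (NA when not computable).
#' @slot sensitivity,specificity numeric scalars, NA when the denominator is
#'   empty (reported as missing, never as 0).
#' @slot restrictedTerm character; term id of the restricted re-analysis or
#'   NA.
#' @slot restricted list; zero or one ConcordanceReport for the restriction.
#' @export
setClass("ConcordanceReport",
         representation(common = "data.frame", quadrant = "matrix",
                        nCommon = "integer", nSameDirection = "integer",
                        nBothUp = "integer", nExcludedZeroDelta = "integer",
                        r = "numeric", rP = "numeric", fisherP = "numeric",
                        sensitivity = "numeric", specificity = "numeric",
                        restrictedTerm = "character", restricted = "list"))

setValidity("ConcordanceReport", function(object) {
  msg <- character(0)
  q <- object@quadrant
  if (!identical(dim(q), c(2L, 2L))) msg <- c(msg, "quadrant must be 2x2")
  else {
    if (object@nCommon != sum(q) + object@nExcludedZeroDelta)
      msg <- c(msg, "nCommon must equal quadrant total + zero-delta exclusions")
    if (object@nSameDirection != q[1, 1] + q[2, 2])
      msg <- c(msg, "nSameDirection must be the concordant diagonal")
    if (object@nBothUp != q[1, 1])
      msg <- c(msg, "nBothUp must be the up/up cell")
  }
  for (s in c("sensitivity", "specificity")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1)) msg <- c(msg, paste(s, "outside [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConcordanceReport", function(object) {
  cat("ConcordanceReport:", object@nCommon, "genes significant in both systems\n")
  cat("  same direction:", object@nSameDirection,
      "| both up:", object@nBothUp,
      "| zero-delta excluded:", object@nExcludedZeroDelta, "\n")
  cat(sprintf("  r = %.3f (p = %.3g), Fisher p = %.3g\n",
              object@r, object@rP, object@fisherP))
  cat(sprintf("  prediction sensitivity = %s, specificity = %s\n",
              fmtProp(object@sensitivity), fmtProp(object@specificity)))
  if (length(object@restricted))
    cat("  restricted to", object@restrictedTerm, ":",
        object@restricted[[1]]@nCommon, "genes, sensitivity",
        fmtProp(object@restricted[[1]]@sensitivity), ", specificity",
        fmtProp(object@restricted[[1]]@specificity), "\n")
})

fmtProp <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)

#' Drug-attenuation report
#'
#' Result container of [attenuationAnalysis()]: among genes significantly
#' induced by the insult (contrast M-S), how many are pushed back down under
#' the drug (contrast F-M), plus the correlation between the two sets of
#' log2 changes.
#'
#' @slot table data.frame: gene_id, delta_MS, delta_FM, induced, reversed
#'   over the genes significant for the insult contrast.
#' @slot nInduced,nInducedReversed,nFKSignificant integer scalars.
#' @slot fractionReversed numeric, NA when no gene is induced.
#' @slot r numeric; correlation of delta_MS and delta_FM over the
#'   insult-significant genes (NA when degenerate).
#' @export
setClass("AttenuationReport",
         representation(table = "data.frame", nInduced = "integer",
                        nInducedReversed = "integer",
                        nFKSignificant = "integer",
                        fractionReversed = "numeric", r = "numeric"))

setValidity("AttenuationReport", function(object) {
  msg <- character(0)
  if (object@nInducedReversed > object@nInduced)
    msg <- c(msg, "nInducedReversed cannot exceed nInduced")
  f <- object@fractionReversed
  if (!is.na(f) && (f < 0 || f > 1))
    msg <- c(msg, "fractionReversed outside [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AttenuationReport", function(object) {
  cat("AttenuationReport:", object@nInduced, "insult-induced genes;",
      object@nInducedReversed, "reversed under drug (fraction",
      fmtProp(object@fractionReversed), ")\n")
  cat(sprintf("  drug-contrast significant genes: %d; r(delta_MS, delta_FM) = %.3f\n",
              object@nFKSignificant, object@r))
})
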