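#' Accessors for xconcord containers
#'
#' @param object a package container object.
#' @return \code{intensities} and \code{calls} return the probeset-level
#'   matrices; \code{log2expr} the gene-level log2 matrix; \code{quadrantTable}
#'   the 2x2 contingency matrix; \code{annotationPairs} and \code{termTable}
#'   the two tables of a \linkS4class{GOAnnotation}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ProbesetExperiment",
          function(object) assay(object, "intensity"))

#' @rdname accessors
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))
#' @rdname accessors
#' @export
setMethod("calls", "ProbesetExperiment",
          function(object) assay(object, "call"))

#' @rdname accessors
#' @export
setGeneric("log2expr", function(object) standardGeneric("log2expr"))
#' @rdname accessors
#' @export
setMethod("log2expr", "GeneExperiment",
          function(object) assay(object, "log2expr"))

#' @rdname accessors
#' @export
setGeneric("annotationPairs", function(object) standardGeneric("annotationPairs"))
#' @rdname accessors
#' @export
setMethod("annotationPairs", "GOAnnotation", function(object) object@pairs)

#' @rdname accessors
#' @export
setGeneric("termTable", function(object) standardGeneric("termTable"))
#' @rdname accessors
#' @export
setMethod("termTable", "GOAnnotation", function(object) object@terms)

#' @rdname accessors
#' @export
setGeneric("isExpanded", function(object) standardGeneric("isExpanded"))
#' @rdname accessors
#' @export
setMethod("isExpanded", "GOAnnotation", function(object) object@expanded)

#' @rdname accessors
#' @export
setGeneric("quadrantTable", function(object) standardGeneric("quadrantTable"))
#' @rdname accessors
#' @export
setMethod("quadrantTable", "ConcordanceReport", function(object) object@quadrant)

#' @rdname accessors
#' @export
setGeneric("commonGenes", function(object) standardGeneric("commonGenes"))
#' @rdname accessors
#' @export
setMethod("commonGenes", "ConcordanceReport", function(object) object@common)

#' Scalar concordance metrics as a one-row data.frame
#'
#' Flattens a \linkS4class{ConcordanceReport} (and, if present, its
#' GO-restricted companion) into plot-/file-ready rows.
#'
#' @param object a ConcordanceReport.
#' @return data.frame with one row per analysis (global, restricted).
#' @export
setGeneric("concordanceMetrics",
           function(object) standardGeneric("concordanceMetrics"))

#' @rdname concordanceMetrics
#' @export
setMethod("concordanceMetrics", "ConcordanceReport", function(object) {
  row <- function(o, label) {
    q <- o@quadrant
    data.frame(analysis = label,
               n_common = o@nCommon,
               n_same_direction = o@nSameDirection,
               n_both_up = o@nBothUp,
               n_excluded_zero_delta = o@nExcludedZeroDelta,
               a = q[1, 1], b = q[1, 2], c = q[2, 1], d = q[2, 2],
               r = o@r, r_p = o@rP, fisher_p = o@fisherP,
               sensitivity = o@sensitivity, specificity = o@specificity,
               stringsAsFactors = FALSE)
  }
  out <- row(object, "global")
  if (length(object@restricted))
    out <- rbind(out, row(object@restricted[[1]],
                          paste0("restricted:", object@restrictedTerm)))
  out
})
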