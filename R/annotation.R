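#' Expand a GO annotation to ancestor closure
#'
#' Propagates every gene-term membership up the parent relation declared in
#' the term table: if a gene is annotated to a term, it is annotated to all
#' of that term's ancestors. Duplicate pairs are removed. The parent
#' relation must be acyclic.
#'
#' Expansion is idempotent: expanding an already-expanded annotation
#' changes nothing.
#'
#' @param annotation a \linkS4class{GOAnnotation}.
#' @return a \linkS4class{GOAnnotation} with \code{expanded = TRUE}.
#' @examples
#' terms <- data.frame(term_id = c("t_root", "t_child"),
#'                     term_name = c("root", "child"),
#'                     parent_ids = c("", "t_root"))
#' pairs <- data.frame(gene_id = "g1", term_id = "t_child")
#' expandAnnotation(GOAnnotation(pairs, terms))
#' @export
expandAnnotation <- function(annotation) {
  stopifnot(is(annotation, "GOAnnotation"))
  terms <- termTable(annotation)
  parents <- parentList(terms)
  anc <- ancestorClosure(parents)
  pairs <- unique(annotationPairs(annotation))
  extra <- lapply(seq_len(nrow(pairs)), function(i) {
    up <- anc[[pairs$term_id[i]]]
    if (is.null(up) || !length(up)) return(NULL)
    data.frame(gene_id = pairs$gene_id[i], term_id = up,
               stringsAsFactors = FALSE)
  })
  out <- unique(rbind(pairs, do.call(rbind, extra)))
  out <- out[order(out$gene_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  GOAnnotation(out, terms, expanded = TRUE)
}

parentList <- function(terms) {
  p <- strsplit(terms$parent_ids, ",", fixed = TRUE)
  p <- lapply(p, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
  names(p) <- terms$term_id
  p
}

## memoised DFS over the parent DAG; detects cycles and names an offender
ancestorClosure <- function(parents) {
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  state <- integer(length(parents))  # 0 unseen, 1 on stack, 2 done
  names(state) <- names(parents)
  visit <- function(t) {
    if (!t %in% names(parents)) return(character(0))
    if (state[[t]] == 1L)
      stopFmt("cycle in term parent relation involving '", t, "'")
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    up <- character(0)
    for (p in parents[[t]]) up <- c(up, p, visit(p))
    anc[[t]] <<- unique(up)
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in names(parents)) visit(t)
  anc
}

#' Genes annotated to a term
#'
#' @param annotation a \linkS4class{GOAnnotation} (typically expanded).
#' @param termId term identifier.
#' @return character vector of gene ids (empty when the term has no genes).
#' @export
genesForTerm <- function(annotation, termId) {
  if (!(termId %in% termTable(annotation)$term_id) &&
      !(termId %in% annotationPairs(annotation)$term_id))
    stopFmt("term '", termId, "' absent from annotation")
  p <- annotationPairs(annotation)
  unique(p$gene_id[p$term_id == termId])
}
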