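#' Read a probeset intensity + detection-call matrix pair
#'
#' Reads two TSV files of identical shape: the first column is
#' \code{probeset_id}, the remaining columns are samples. The intensity file
#' holds linear-scale non-negative values; the call file holds detection
#' calls \code{P}/\code{M}/\code{A}.
#'
#' @param intensityPath path to the intensity TSV.
#' @param callPath path to the call TSV.
#' @return a \linkS4class{ProbesetExperiment} with row/column order as on
#'   disk.
#' @export
readProbesetMatrix <- function(intensityPath, callPath) {
  xi <- readTsv(intensityPath)
  xc <- readTsv(callPath)
  toMat <- function(df, path) {
    if (ncol(df) < 2) stopFmt(path, ": no sample columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stopFmt(path, ": duplicated probeset_id '", ids[duplicated(ids)][1], "'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    m
  }
  mi <- toMat(xi, intensityPath)
  mc <- toMat(xc, callPath)
  miss <- c(setdiff(colnames(mi), colnames(mc)),
            setdiff(colnames(mc), colnames(mi)))
  if (length(miss))
    stopFmt("sample '", miss[1], "' present in only one of the two files")
  missRow <- c(setdiff(rownames(mi), rownames(mc)),
               setdiff(rownames(mc), rownames(mi)))
  if (length(missRow))
    stopFmt("probeset '", missRow[1], "' present in only one of the two files")
  mc <- mc[rownames(mi), colnames(mi), drop = FALSE]
  suppressWarnings(storage.mode(mi) <- "double")
  bad <- which(!is.finite(mi), arr.ind = TRUE)
  if (nrow(bad))
    stopFmt("non-numeric intensity at probeset '", rownames(mi)[bad[1, 1]],
            "', sample '", colnames(mi)[bad[1, 2]], "'")
  bad <- which(mi < 0, arr.ind = TRUE)
  if (nrow(bad))
    stopFmt("negative intensity at probeset '", rownames(mi)[bad[1, 1]],
            "', sample '", colnames(mi)[bad[1, 2]], "'")
  mc[] <- as.character(mc)
  bad <- which(!(mc %in% VALID_CALLS), arr.ind = TRUE)
  if (length(bad))
    stopFmt("invalid detection call '", mc[bad[1]],
            "' (expected one of P, M, A)")
  ProbesetExperiment(mi, mc)
}

#' Write a ProbesetExperiment as an intensity + call TSV pair
#'
#' Inverse of [readProbesetMatrix()]; intensities are written with 6
#' significant digits.
#'
#' @param pe a \linkS4class{ProbesetExperiment}.
#' @param intensityPath,callPath output paths.
#' @return invisibly, the two paths.
#' @export
writeProbesetMatrix <- function(pe, intensityPath, callPath) {
  di <- data.frame(probeset_id = rownames(pe),
                   fmtNum(intensities(pe)), check.names = FALSE)
  dc <- data.frame(probeset_id = rownames(pe), calls(pe), check.names = FALSE)
  writeTsv(di, intensityPath)
  writeTsv(dc, callPath)
  invisible(c(intensityPath, callPath))
}

#' Validate a study-design table
#'
#' A design has columns \code{sample_id}, \code{experiment},
#' \code{condition} and optional \code{pair_id} (empty/NA = unpaired).
#' Duplicated sample ids are rejected; a pair id must link exactly two
#' samples of different conditions.
#'
#' @param design data.frame.
#' @return the validated design with \code{pair_id} normalised to NA for
#'   unpaired samples.
#' @export
validateDesign <- function(design) {
  need <- c("sample_id", "experiment", "condition")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stopFmt("design lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(design) == 0) stopFmt("design has no samples")
  design$sample_id <- as.character(design$sample_id)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup)) stopFmt("duplicated sample_id '", dup[1], "' in design")
  if (!("pair_id" %in% colnames(design))) design$pair_id <- NA_character_
  design$pair_id <- as.character(design$pair_id)
  design$pair_id[!is.na(design$pair_id) & design$pair_id == ""] <- NA_character_
  paired <- design[!is.na(design$pair_id), , drop = FALSE]
  if (nrow(paired)) {
    for (pid in unique(paired$pair_id)) {
      grp <- paired[paired$pair_id == pid, , drop = FALSE]
      if (nrow(grp) != 2)
        stopFmt("pair_id '", pid, "' links ", nrow(grp),
                " samples (exactly 2 required)")
      if (grp$condition[1] == grp$condition[2])
        stopFmt("pair_id '", pid, "' links two samples of condition '",
                grp$condition[1], "'")
    }
  }
  design[c("sample_id", "experiment", "condition", "pair_id")]
}

#' Read a study-design TSV
#'
#' @param path TSV with columns sample_id, experiment, condition, pair_id
#'   (pair_id may be empty).
#' @return validated design data.frame.
#' @export
readDesign <- function(path) {
  df <- readTsv(path, colClasses = "character")
  if (nrow(df) == 0) stopFmt(path, ": no samples")
  validateDesign(df)
}

#' @rdname readDesign
#' @param design a validated design data.frame.
#' @export
writeDesign <- function(design, path) {
  d <- design
  d$pair_id[is.na(d$pair_id)] <- ""
  writeTsv(d, path)
}

#' Read a probeset-to-gene mapping table
#'
#' Columns: \code{probeset_id}, \code{gene_id}, optional
#' \code{gene_symbol}. A probeset mapping to more than one gene is rejected
#' (many-to-one gene averaging is defined; one-to-many is not).
#'
#' @param path TSV path.
#' @return data.frame with the three columns, duplicates removed.
#' @export
readGeneMap <- function(path) {
  df <- readTsv(path, colClasses = "character")
  validateGeneMap(df)
}

#' @rdname readGeneMap
#' @param map data.frame with probeset_id and gene_id columns.
#' @export
validateGeneMap <- function(map) {
  need <- c("probeset_id", "gene_id")
  miss <- setdiff(need, colnames(map))
  if (length(miss)) stopFmt("map lacks columns: ", paste(miss, collapse = ", "))
  if (!("gene_symbol" %in% colnames(map))) map$gene_symbol <- map$gene_id
  map <- unique(map[c("probeset_id", "gene_id", "gene_symbol")])
  multi <- unique(map$probeset_id[duplicated(map$probeset_id)])
  if (length(multi))
    stopFmt("probeset '", multi[1], "' maps to multiple gene_ids")
  map
}

#' @rdname readGeneMap
#' @export
writeGeneMap <- function(map, path) writeTsv(map, path)

#' Read gene-term annotation and term tables
#'
#' \code{annotationPath} has columns \code{gene_id}, \code{term_id};
#' \code{termsPath} has \code{term_id}, \code{term_name},
#' \code{parent_ids} (comma-joined, may be empty). The returned annotation
#' is raw (not ancestor-expanded); apply [expandAnnotation()] before use in
#' ranking.
#'
#' @param annotationPath,termsPath TSV paths.
#' @return a \linkS4class{GOAnnotation} with \code{expanded = FALSE}.
#' @export
readAnnotation <- function(annotationPath, termsPath) {
  pairs <- readTsv(annotationPath, colClasses = "character")
  terms <- readTsv(termsPath, colClasses = "character")
  if (!("parent_ids" %in% colnames(terms))) terms$parent_ids <- ""
  terms$parent_ids[is.na(terms$parent_ids)] <- ""
  GOAnnotation(pairs, terms, expanded = FALSE)
}

#' @rdname readAnnotation
#' @param annotation a \linkS4class{GOAnnotation}.
#' @export
writeAnnotation <- function(annotation, annotationPath, termsPath) {
  writeTsv(annotationPairs(annotation), annotationPath)
  writeTsv(termTable(annotation), termsPath)
  invisible(c(annotationPath, termsPath))
}

#' Write / read a gene-level log2 expression matrix
#'
#' @param ge a \linkS4class{GeneExperiment}.
#' @param path TSV path; first column \code{gene_id}, then per-sample log2
#'   values at 6 significant digits.
#' @return \code{readGeneMatrix} returns a \linkS4class{GeneExperiment}.
#' @export
writeGeneMatrix <- function(ge, path) {
  df <- data.frame(gene_id = rownames(ge), fmtNum(log2expr(ge)),
                   check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeGeneMatrix
#' @export
readGeneMatrix <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  new("GeneExperiment", SummarizedExperiment(assays = list(log2expr = m)))
}

#' Read / write a differential-expression table
#'
#' @param path TSV with columns gene_id, contrast, delta, t_stat, df, p, q.
#' @return data.frame sorted by p ascending, ties by gene_id.
#' @export
readDETable <- function(path) {
  df <- readTsv(path)
  validateDETable(df)
}

#' @rdname readDETable
#' @param de a differential table data.frame.
#' @export
writeDETable <- function(de, path) {
  de <- validateDETable(de)
  num <- c("delta", "t_stat", "df", "p", "q")
  de[num] <- lapply(de[num], function(x) signif(x, 9))
  writeTsv(de, path)
}

validateDETable <- function(de) {
  need <- c("gene_id", "contrast", "delta", "t_stat", "df", "p", "q")
  miss <- setdiff(need, colnames(de))
  if (length(miss)) stopFmt("DE table lacks columns: ", paste(miss, collapse = ", "))
  if (any(de$p < 0 | de$p > 1, na.rm = TRUE)) stopFmt("p outside [0,1]")
  if (any(de$q < 0 | de$q > 1, na.rm = TRUE)) stopFmt("q outside [0,1]")
  de[order(de$p, de$gene_id), need]
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration with keys \code{alpha}, \code{seed},
#' \code{go_terms}, \code{min_term_size}, \code{max_term_size} and a
#' \code{paths} block; missing keys fall back to defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return named list with validated fields.
#' @importFrom yaml read_yaml
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- list(alpha = 0.05, seed = 1L,
              go_terms = c("GO:0009605", "GO:0009611",
                           "GO:0002376", "GO:0006954"),
              min_term_size = 2L, max_term_size = NA_integer_,
              paths = list())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stopFmt("alpha must lie in (0, 1)")
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stopFmt("seed must be a nonnegative integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
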