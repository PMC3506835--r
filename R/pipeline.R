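#' Run the full cross-system analysis pipeline
#'
#' Sequences all stages with one configuration: (optional) simulation,
#' per-experiment preprocessing (detection-call filtering and gene
#' collapsing), differential expression (three-condition ANOVA screen,
#' Welch contrasts M-S and F-M, paired in vitro contrast), rank-based GO
#' association per contrast, and the concordance stage (global and
#' GO-restricted concordance, attenuation analysis, heatmap ordering,
#' Venn counts). All plot-ready tables plus a machine-readable run
#' manifest are written under \code{outdir}.
#'
#' On a stage error the partially written outputs of that stage are
#' renamed with a \code{.partial} suffix and the error is re-raised with
#' the stage name.
#'
#' @param outdir output directory (created if missing).
#' @param config pipeline configuration (see [readPipelineConfig()]).
#' @param sim simulation configuration ([simConfig()]); used when
#'   \code{inputs} is NULL. Its seed defaults to the pipeline seed.
#' @param inputs optional named list of input paths
#'   (\code{invivoIntensity}, \code{invivoCall}, \code{invivoDesign},
#'   \code{invitroIntensity}, \code{invitroCall}, \code{invitroDesign},
#'   \code{map}, \code{annotation}, \code{terms}) to run on real-format
#'   data instead of simulating.
#' @return the run manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @importFrom jsonlite write_json
#' @export
runPipeline <- function(outdir, config = readPipelineConfig(), sim = NULL,
                        inputs = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha
  manifest <- list(config = config[c("alpha", "seed", "go_terms",
                                     "min_term_size", "max_term_size")],
                   version = as.character(utils::packageVersion("xconcord")),
                   stages = list())
  emitted <- character(0)

  stage <- function(name, files, fun) {
    t0 <- proc.time()[["elapsed"]]
    paths <- file.path(outdir, files)
    res <- tryCatch(fun(paths), error = function(e) {
      for (p in paths[file.exists(paths)]) file.rename(p, paste0(p, ".partial"))
      stopFmt("stage '", name, "' failed: ", conditionMessage(e))
    })
    counts <- vapply(paths, function(p) {
      if (file.exists(p)) length(readLines(p)) - 1L else NA_integer_
    }, 1L)
    manifest$stages[[name]] <<- list(
      outputs = as.list(stats::setNames(counts, files)),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    emitted <<- c(emitted, paths[file.exists(paths)])
    res
  }

  ## -- inputs ---------------------------------------------------------
  if (is.null(inputs)) {
    if (is.null(sim)) sim <- simConfig(seed = config$seed)
    study <- stage("simulate",
                   c("invivo_intensities.tsv", "invivo_calls.tsv",
                     "invivo_design.tsv", "invitro_intensities.tsv",
                     "invitro_calls.tsv", "invitro_design.tsv", "map.tsv",
                     "annotation.tsv", "terms.tsv", "truth.tsv"),
                   function(paths) {
      st <- simulateStudy(sim)
      writeProbesetMatrix(st$invivo, paths[1], paths[2])
      writeDesign(st$designInvivo, paths[3])
      writeProbesetMatrix(st$invitro, paths[4], paths[5])
      writeDesign(st$designInvitro, paths[6])
      writeGeneMap(st$map, paths[7])
      writeAnnotation(st$annotation, paths[8], paths[9])
      writeTsv(st$truth, paths[10])
      st
    })
    invivo <- study$invivo; invitro <- study$invitro
    designInvivo <- study$designInvivo; designInvitro <- study$designInvitro
    map <- study$map; annRaw <- study$annotation
  } else {
    invivo <- readProbesetMatrix(inputs$invivoIntensity, inputs$invivoCall)
    designInvivo <- readDesign(inputs$invivoDesign)
    invitro <- readProbesetMatrix(inputs$invitroIntensity, inputs$invitroCall)
    designInvitro <- readDesign(inputs$invitroDesign)
    map <- readGeneMap(inputs$map)
    annRaw <- readAnnotation(inputs$annotation, inputs$terms)
  }
  annotation <- expandAnnotation(annRaw)

  ## -- preprocess -----------------------------------------------------
  pre <- stage("preprocess",
               c("gene_matrix_invivo.tsv", "gene_matrix_invitro.tsv",
                 "filter_report.tsv"),
               function(paths) {
    a <- preprocessExperiment(invivo, designInvivo, map)
    b <- preprocessExperiment(invitro, designInvitro, map)
    writeGeneMatrix(a$genes, paths[1])
    writeGeneMatrix(b$genes, paths[2])
    writeTsv(cbind(experiment = c("invivo", "invitro"),
                   rbind(a$report, b$report)), paths[3])
    list(invivo = a$genes, invitro = b$genes)
  })

  ## -- differential expression ---------------------------------------
  de <- stage("de", c("de_anova_SMF.tsv", "de_M-S.tsv", "de_F-M.tsv",
                      "de_LPS-control.tsv"),
              function(paths) {
    anova <- runAnovaScreen(pre$invivo, designInvivo, c("S", "M", "F"))
    ms <- runWelchContrast(pre$invivo, designInvivo, "S", "M")
    fm <- runWelchContrast(pre$invivo, designInvivo, "M", "F")
    lps <- runPairedContrast(pre$invitro, designInvitro, "control", "LPS")
    writeDETable(anova, paths[1]); writeDETable(ms, paths[2])
    writeDETable(fm, paths[3]); writeDETable(lps, paths[4])
    list(anova = anova, ms = ms, fm = fm, lps = lps)
  })

  ## -- GO ranking -----------------------------------------------------
  go <- stage("go", c("go_M-S.tsv", "go_F-M.tsv", "go_LPS-control.tsv",
                      "venn_counts.tsv"),
              function(paths) {
    tabs <- list()
    for (i in seq_along(cn <- c("ms", "fm", "lps"))) {
      ranked <- rankGenes(de[[cn[i]]], alpha)
      tabs[[cn[i]]] <- if (nrow(ranked) >= 4)
        goAssociations(ranked, annotation, config$min_term_size,
                       config$max_term_size)
      else data.frame(term_id = character(0), term_name = character(0),
                      n_genes = integer(0), p = numeric(0),
                      p_fdr = numeric(0), sign = integer(0),
                      signed_score = numeric(0))
      writeTsv(tabs[[cn[i]]], paths[i])
    }
    fkGenes <- de$fm$gene_id[de$fm$p < alpha]
    venn <- if (length(fkGenes))
      termMembershipCounts(fkGenes, annotation, config$go_terms)$regions
    else data.frame(mask = character(0), terms = character(0), n = integer(0))
    writeTsv(venn, paths[4])
    tabs
  })

  ## -- concordance ----------------------------------------------------
  restrictTerm <- config$go_terms[length(config$go_terms)]
  conc <- stage("concord",
                c("concordance.tsv", "concordance_report.tsv",
                  "attenuation_report.tsv", "heatmap_order.tsv"),
                function(paths) {
    rep <- concordanceAnalysis(de$ms, de$lps, alpha, annotation,
                               restrictTerm = restrictTerm)
    att <- attenuationAnalysis(de$ms, de$fm, alpha)
    writeTsv(commonGenes(rep), paths[1])
    writeTsv(concordanceMetrics(rep), paths[2])
    writeTsv(data.frame(n_induced = att@nInduced,
                        n_induced_reversed = att@nInducedReversed,
                        fraction_reversed = att@fractionReversed,
                        n_FK_significant = att@nFKSignificant,
                        r = att@r), paths[3])
    fkGenes <- de$fm$gene_id[de$fm$p < alpha]
    hm <- intersect(fkGenes, genesForTerm(annotation, restrictTerm))
    ord <- if (length(hm)) heatmapOrder(hm, de$ms, de$lps, alpha)
    else data.frame(gene_id = character(0), delta_MS = numeric(0),
                    invitro_significant = logical(0))
    writeTsv(ord, paths[4])
    list(report = rep, attenuation = att)
  })

  manifest$files <- basename(emitted)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(de = de, go = go, concordance = conc$report,
                   attenuation = conc$attenuation)))
}
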