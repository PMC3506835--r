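#' Simulation configuration
#'
#' Parameters of the paired in vivo / in vitro synthetic study. The
#' defaults emulate the two designs the pipeline targets: a
#' three-condition insult experiment (sham S, insult M, insult + drug F,
#' n = 3 each) and a paired stimulation experiment (4 matched
#' control/stimulated preparations plus 2 unpaired control cultures), a
#' shared inflammatory program of 400 genes induced in both systems with a
#' mean log2 effect of 1.5, drug attenuation removing 80\% of the
#' program's insult effect, probeset multiplicity of 1-3 per gene,
#' log2-normal intensity noise (sd 0.25), and intensity-dependent Absent
#' calls.
#'
#' @param nGenes number of genes.
#' @param probesetsPerGene integer range (min, max) of probesets per gene,
#'   uniform.
#' @param nPerGroup in vivo samples per condition (S, M, F).
#' @param nPairs matched in vitro control/stimulated pairs.
#' @param nUnpairedControls extra unpaired in vitro control cultures.
#' @param nProgram genes of the shared inflammatory program.
#' @param programEffect mean log2 induction of program genes in both
#'   systems (per-gene effects vary uniformly within +/- 25\%).
#' @param attenuation fraction of the program's insult effect removed
#'   under the drug, in [0, 1].
#' @param nSpecificInvivo,nSpecificInvitro system-specific responsive
#'   genes per system.
#' @param specificEffect mean absolute log2 effect of system-specific
#'   genes (random sign).
#' @param baselineMean,baselineSd log2-scale baseline expression
#'   distribution.
#' @param sigma residual log2 noise sd.
#' @param pairSd sd of the per-preparation random intercept of the paired
#'   in vitro design.
#' @param probesetOffsetSd sd of the per-probeset log2 offset.
#' @param detectTheta log2 intensity at which the Absent-call probability
#'   is 50\%.
#' @param detectSlope logistic slope (log2 units) of the detection model.
#' @param marginalProb probability of a Marginal (rather than Present)
#'   call for a detected cell.
#' @param nNoiseTerms random background GO terms.
#' @param seed nonnegative integer RNG seed.
#' @return validated configuration list.
#' @export
simConfig <- function(nGenes = 10000, probesetsPerGene = c(1, 3),
                      nPerGroup = 3, nPairs = 4, nUnpairedControls = 2,
                      nProgram = 400, programEffect = 1.5,
                      attenuation = 0.8, nSpecificInvivo = 300,
                      nSpecificInvitro = 300, specificEffect = 1.0,
                      baselineMean = 7, baselineSd = 1.5, sigma = 0.25,
                      pairSd = 0.25, probesetOffsetSd = 0.5,
                      detectTheta = 5, detectSlope = 1,
                      marginalProb = 0.05, nNoiseTerms = 25, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$nGenes, cfg$nProgram, cfg$nSpecificInvivo,
              cfg$nSpecificInvitro, cfg$nPerGroup, cfg$nPairs,
              cfg$nUnpairedControls)
  if (any(counts < 0)) stopFmt("counts must be >= 0")
  if (cfg$nProgram + cfg$nSpecificInvivo + cfg$nSpecificInvitro > cfg$nGenes)
    stopFmt("program + specific genes exceed nGenes")
  if (cfg$sigma <= 0) stopFmt("sigma must be > 0")
  if (cfg$attenuation < 0 || cfg$attenuation > 1)
    stopFmt("attenuation must lie in [0, 1]")
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stopFmt("seed must be a nonnegative integer")
  if (length(cfg$probesetsPerGene) != 2 ||
      cfg$probesetsPerGene[1] > cfg$probesetsPerGene[2] ||
      cfg$probesetsPerGene[1] < 1)
    stopFmt("probesetsPerGene must be an increasing integer pair >= 1")
  class(cfg) <- "xc_sim_config"
  cfg
}

#' Generate a paired synthetic study with known ground truth
#'
#' Builds probeset-level intensity/call matrices and designs for both
#' systems, the probeset-to-gene map, a GO annotation whose
#' inflammatory-response-like term holds exactly the program genes, and
#' the ground-truth effect table. Gene-level log2 means are baseline +
#' condition effect (program genes: +s in M and in the stimulated
#' condition, +(1 - attenuation) * s in F; system-specific effects in
#' their own system only); paired in vitro samples share a per-preparation
#' random intercept; each probeset adds a fixed offset; observations are
#' 2^(mean + offsets + Normal(0, sigma)); Absent calls follow a logistic
#' function of the log2 intensity. Fully reproducible from the seed.
#'
#' @param config a configuration from [simConfig()].
#' @return list with elements \code{invivo}, \code{invitro}
#'   (\linkS4class{ProbesetExperiment}), \code{designInvivo},
#'   \code{designInvitro}, \code{map}, \code{annotation} (raw, not
#'   expanded), \code{truth} (data.frame), \code{programTerm},
#'   \code{config}.
#' @export
simulateStudy <- function(config = simConfig()) {
  stopifnot(inherits(config, "xc_sim_config"))
  set.seed(config$seed)
  nG <- config$nGenes
  geneIds <- sprintf("g%05d", seq_len(nG))

  roles <- rep("null", nG)
  pick <- sample(nG, config$nProgram + config$nSpecificInvivo +
                   config$nSpecificInvitro)
  prog <- pick[seq_len(config$nProgram)]
  spA <- pick[config$nProgram + seq_len(config$nSpecificInvivo)]
  spB <- pick[config$nProgram + config$nSpecificInvivo +
                seq_len(config$nSpecificInvitro)]
  roles[prog] <- "program"; roles[spA] <- "specific_invivo"
  roles[spB] <- "specific_invitro"

  s <- config$programEffect
  effProg <- s * stats::runif(length(prog), 0.75, 1.25)
  effA <- config$specificEffect * stats::runif(length(spA), 0.75, 1.25) *
    sample(c(-1, 1), length(spA), replace = TRUE)
  effB <- config$specificEffect * stats::runif(length(spB), 0.75, 1.25) *
    sample(c(-1, 1), length(spB), replace = TRUE)

  dMS <- dLPS <- rep(0, nG)
  dMS[prog] <- effProg; dLPS[prog] <- effProg
  dMS[spA] <- effA; dLPS[spB] <- effB
  ## the drug removes a fraction of every insult-induced change
  dFS <- (1 - config$attenuation) * dMS

  truth <- data.frame(gene_id = geneIds, role = roles,
                      program = roles == "program",
                      delta_MS = dMS, delta_FS = dFS, delta_LPS = dLPS,
                      stringsAsFactors = FALSE)

  baseline <- stats::rnorm(nG, config$baselineMean, config$baselineSd)

  ## probeset scaffold, shared between the two systems (same chip)
  kPs <- sample(config$probesetsPerGene[1]:config$probesetsPerGene[2],
                nG, replace = TRUE)
  psGene <- rep(seq_len(nG), kPs)
  psIds <- sprintf("ps%06d", seq_along(psGene))
  psOffset <- stats::rnorm(length(psGene), 0, config$probesetOffsetSd)
  map <- data.frame(probeset_id = psIds, gene_id = geneIds[psGene],
                    gene_symbol = toupper(geneIds[psGene]),
                    stringsAsFactors = FALSE)

  nPer <- config$nPerGroup
  condV <- rep(c("S", "M", "F"), each = nPer)
  vivoIds <- paste0(rep(c("S", "M", "F"), each = nPer), seq_len(nPer))
  vivoEff <- cbind(S = rep(0, nG), M = dMS, F = dFS)
  muVivo <- baseline[psGene] + psOffset +
    vivoEff[psGene, condV, drop = FALSE]
  designInvivo <- data.frame(sample_id = vivoIds, experiment = "invivo",
                             condition = condV, pair_id = NA_character_,
                             stringsAsFactors = FALSE)
  invivo <- drawMatrix(muVivo, psIds, vivoIds, config)

  nPr <- config$nPairs
  nUc <- config$nUnpairedControls
  ctrlIds <- paste0("ctrl", seq_len(nPr + nUc))
  lpsIds <- paste0("lps", seq_len(nPr))
  pairInt <- stats::rnorm(nPr + nUc, 0, config$pairSd)
  muCtrl <- sapply(seq_len(nPr + nUc), function(j)
    baseline[psGene] + psOffset + pairInt[j])
  muLps <- sapply(seq_len(nPr), function(j)
    baseline[psGene] + psOffset + pairInt[j] + dLPS[psGene])
  muVitro <- cbind(muCtrl, muLps)
  vitroIds <- c(ctrlIds, lpsIds)
  designInvitro <- data.frame(
    sample_id = vitroIds, experiment = "invitro",
    condition = c(rep("control", nPr + nUc), rep("LPS", nPr)),
    pair_id = c(paste0("p", seq_len(nPr)), rep(NA_character_, nUc),
                paste0("p", seq_len(nPr))),
    stringsAsFactors = FALSE)
  invitro <- drawMatrix(muVitro, psIds, vitroIds, config)

  ann <- simAnnotation(geneIds, prog, config)

  list(invivo = ProbesetExperiment(intensities(invivo), calls(invivo),
                                   designInvivo),
       invitro = ProbesetExperiment(intensities(invitro), calls(invitro),
                                    designInvitro),
       designInvivo = designInvivo, designInvitro = designInvitro,
       map = map, annotation = ann, truth = truth,
       programTerm = "GO:0006954", config = config)
}

## draw intensities and calls given per-cell log2 means
drawMatrix <- function(mu, rowIds, colIds, config) {
  mu <- as.matrix(mu)
  val <- mu + stats::rnorm(length(mu), 0, config$sigma)
  pAbs <- stats::plogis((config$detectTheta - val) / config$detectSlope)
  u <- stats::runif(length(val))
  cl <- ifelse(u < pAbs, "A",
               ifelse(u < pAbs + (1 - pAbs) * config$marginalProb, "M", "P"))
  x <- 2^val
  dimnames(x) <- list(rowIds, colIds)
  cl <- matrix(cl, nrow = nrow(x), dimnames = dimnames(x))
  ProbesetExperiment(x, cl)
}

## GO scaffold: a small true hierarchy whose inflammatory-response-like
## term holds exactly the program genes, plus random background terms
simAnnotation <- function(geneIds, prog, config) {
  terms <- data.frame(
    term_id = c("GO:0008150", "GO:0050896", "GO:0009605", "GO:0009611",
                "GO:0006954", "GO:0002376"),
    term_name = c("biological_process", "response to stimulus",
                  "response to external stimulus", "response to wounding",
                  "inflammatory response", "immune system process"),
    parent_ids = c("", "GO:0008150", "GO:0050896", "GO:0009605",
                   "GO:0009611", "GO:0008150"),
    stringsAsFactors = FALSE)
  nG <- length(geneIds)
  pairs <- data.frame(gene_id = character(0), term_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(prog))
    pairs <- data.frame(gene_id = geneIds[prog], term_id = "GO:0006954",
                        stringsAsFactors = FALSE)
  ## immune system process: half the program plus unrelated genes
  immune <- c(prog[seq_len(floor(length(prog) / 2))],
              sample(setdiff(seq_len(nG), prog),
                     min(100, nG - length(prog))))
  if (length(immune))
    pairs <- rbind(pairs, data.frame(gene_id = geneIds[immune],
                                     term_id = "GO:0002376"))
  ## dilute the ancestors with direct unrelated annotations
  for (t in c("GO:0009611", "GO:0009605")) {
    extra <- sample(setdiff(seq_len(nG), prog), min(150, nG - length(prog)))
    pairs <- rbind(pairs, data.frame(gene_id = geneIds[extra], term_id = t))
  }
  if (config$nNoiseTerms > 0) {
    for (i in seq_len(config$nNoiseTerms)) {
      tid <- sprintf("T:%04d", i)
      terms <- rbind(terms, data.frame(term_id = tid,
                                       term_name = paste("random process", i),
                                       parent_ids = "GO:0008150"))
      sz <- sample(10:100, 1)
      pairs <- rbind(pairs, data.frame(gene_id = geneIds[sample(nG, sz)],
                                       term_id = tid))
    }
  }
  GOAnnotation(unique(pairs), terms, expanded = FALSE)
}

#' Compare pipeline output against simulation ground truth
#'
#' @param truth ground-truth table from [simulateStudy()].
#' @param deMS insult-contrast differential table (M-S).
#' @param deLPS in vitro differential table (stimulated - control).
#' @param report optional \linkS4class{ConcordanceReport} for the
#'   truth-based sensitivity/specificity of the concordance stage.
#' @param deFM optional drug-contrast table (F-M) for the truth-restricted
#'   reversal fraction.
#' @param goTable optional GO association table for the program-term rank.
#' @param programTerm term id of the designed program.
#' @param alpha significance threshold used by the pipeline.
#' @return list of recovery metrics: \code{rmseMS}, \code{rmseLPS} (RMSE
#'   of estimated vs true log2 change), \code{sensitivity} (fraction of
#'   program genes — among those surviving detection filtering in both
#'   systems — recovered in quadrant I of the concordance),
#'   \code{specificity} (fraction of detected true-null genes kept out of
#'   the common set), \code{fractionReversedTrue} (reversal fraction among
#'   truly induced, detected genes), \code{programTermRank} (1 = most
#'   extreme positive signed score).
#' @export
truthMetrics <- function(truth, deMS, deLPS, report = NULL, deFM = NULL,
                         goTable = NULL, programTerm = "GO:0006954",
                         alpha = 0.05) {
  if (!all(deMS$gene_id %in% truth$gene_id) ||
      !all(deLPS$gene_id %in% truth$gene_id))
    stopFmt("mismatched gene universe between truth and DE tables")
  rmse <- function(de, col) {
    tr <- truth[[col]][match(de$gene_id, truth$gene_id)]
    sqrt(mean((de$delta - tr)^2))
  }
  out <- list(rmseMS = rmse(deMS, "delta_MS"), rmseLPS = rmse(deLPS, "delta_LPS"))
  ## truth labels are evaluated over the genes the concordance stage can
  ## see, i.e. those surviving detection filtering in both systems
  universe <- intersect(deMS$gene_id, deLPS$gene_id)
  progGenes <- intersect(truth$gene_id[truth$program], universe)
  nullGenes <- intersect(truth$gene_id[truth$delta_MS == 0 &
                                         truth$delta_LPS == 0 &
                                         truth$delta_FS == 0], universe)
  if (!is.null(report)) {
    common <- commonGenes(report)
    bothUp <- common$gene_id[common$delta_invivo > 0 & common$delta_invitro > 0]
    out$sensitivity <- if (length(progGenes))
      mean(progGenes %in% bothUp) else NA_real_
    out$specificity <- if (length(nullGenes))
      mean(!(nullGenes %in% common$gene_id)) else NA_real_
  }
  if (!is.null(deFM)) {
    sig <- deMS[deMS$p < alpha & deMS$delta > 0, , drop = FALSE]
    trueInd <- sig$gene_id[sig$gene_id %in%
                             truth$gene_id[truth$delta_MS > 0]]
    if (length(trueInd)) {
      fm <- deFM$delta[match(trueInd, deFM$gene_id)]
      out$fractionReversedTrue <- mean(fm < 0)
    } else out$fractionReversedTrue <- NA_real_
  }
  if (!is.null(goTable) && nrow(goTable)) {
    out$programTermRank <-
      if (programTerm %in% goTable$term_id)
        which(goTable$term_id[order(-goTable$signed_score)] == programTerm)[1]
      else NA_integer_
  }
  out
}
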