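options(xconcord.verbose = FALSE)

## tiny 2-probeset x 2-sample experiment used across io/preprocess tests
toyPE <- function(intensity = matrix(c(100, 50, 200, 80), 2, 2),
                  call = matrix(c("P", "A", "P", "M"), 2, 2)) {
  dimnames(intensity) <- list(c("ps1", "ps2"), c("s1", "s2"))
  dimnames(call) <- dimnames(intensity)
  ProbesetExperiment(intensity, call)
}

toyDesign <- function(samples = c("s1", "s2"),
                      conditions = c("A", "B"),
                      experiment = "invivo") {
  data.frame(sample_id = samples, experiment = experiment,
             condition = conditions, pair_id = NA_character_,
             stringsAsFactors = FALSE)
}

## small but complete synthetic study for integration-level tests
smallStudy <- function(seed = 11, ...) {
  simulateStudy(simConfig(nGenes = 600, nProgram = 60,
                          nSpecificInvivo = 60, nSpecificInvitro = 60,
                          nNoiseTerms = 10, seed = seed, ...))
}

## independent two-sided Fisher oracle via dhyper (distinct code path from
## the log-space implementation under test)
oracleFisher <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- a + b; n1 <- a + c
  if (m1 == 0 || m1 == n || n1 == 0 || n1 == n) return(1)
  ks <- max(0, n1 - (n - m1)):min(m1, n1)
  dens <- stats::dhyper(ks, m1, n - m1, n1)
  sum(dens[dens <= stats::dhyper(a, m1, n - m1, n1) * (1 + 1e-7)])
}

## independent exact rank-sum oracle: enumerate all in-group subsets
oracleRankSum <- function(inRanks, outRanks) {
  allR <- c(inRanks, outRanks)
  k <- length(inRanks)
  sums <- combn(length(allR), k, function(ix) sum(allR[ix]))
  w <- sum(inRanks)
  lo <- mean(sums <= w + 1e-9)
  hi <- mean(sums >= w - 1e-9)
  list(pLower = lo, pUpper = hi, p = min(1, 2 * min(lo, hi)))
}
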