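---
title: "Cross-system concordance of transcriptomic responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-system concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xconcord)
options(xconcord.verbose = FALSE)
```

## The scientific problem

A recurring question in neuroinflammation research is whether the
transcriptional response observed in a whole tissue after an insult — here,
cerebral cortex after experimental focal ischemia — can be attributed to a
particular cell type, and whether a drug that dampens the tissue response
acts on that cell type's program. One way to address it computationally is
to profile the same gene space in two systems: in vivo, with a
three-condition design (sham-operated S, insult M, insult plus drug F), and
in vitro, with the implicated cell type (microglia) stimulated directly
(paired control/LPS cultures). If the insult response is driven by the
cultured cell type, the per-gene effect sizes of the two systems should be
concordant, and the drug's effect in vivo should preferentially undo the
shared program.

`xconcord` implements that comparison as a reusable pipeline over
probeset-level microarray output (linear-scale intensities plus
Present/Marginal/Absent detection calls), with every stage testable against
a synthetic-data generator that knows the ground truth.

## The pipeline, stage by stage

### Detection-call filtering and gene summarization

A probeset is retained when it is detected (call P or M) in **every**
sample of **at least one** condition of its experiment. The rule is applied
per condition label, per experiment, before anything else; an empty result
is legal and propagates as an empty matrix rather than an error. Filtering
is deliberately insensitive to intensities — a brightly hybridizing
probeset flagged Absent everywhere is dropped.

Retained probesets are mapped to genes (a probeset may map to at most one
gene; ambiguous rows are rejected at read time because averaging over
genes is undefined), and each gene's per-sample profile is the **arithmetic
mean of its probesets' linear intensities, log2-transformed afterwards**.
Average-then-transform is a contract, not an accident: by Jensen's
inequality mean-then-log dominates log-then-mean, and the test suite pins
the order. A gene's value uses however many of its probesets survived
filtering; requiring all of them would discard genes whose weakest probeset
sits near the detection threshold.

### Per-gene statistics

All tests are two-sided and operate on the log2 gene matrix:

* a one-way ANOVA screen across the three in vivo conditions,
* Welch unpaired t-tests for the insult (M−S) and drug (F−M) contrasts,
  with Welch–Satterthwaite degrees of freedom,
* a paired t-test for the in vitro contrast, on per-pair differences.
  Samples without a pair identifier are excluded from the paired test and
  counted in the log; this is how a 6-control / 4-stimulated design with 4
  matched pairs is handled.

Genes with zero variance in every group produce sentinel p-values (1 when
means agree, the smallest representable positive double when they do not)
instead of exceptions, so one flat gene can never abort a 10,000-gene run.

Multiple testing uses Storey q-values: the null proportion pi0 is
estimated on the lambda grid 0.05–0.90 (step 0.05) by cubic
smoothing-spline interpolation of `#(p > lambda) / (m (1 - lambda))`
evaluated at lambda = 0.90 and clamped to (0, 1]; q-values are the step-up
quantity `min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`. With pi0
forced to 1 this reduces exactly to Benjamini–Hochberg, which is also
exposed separately and used for GO tables. Below 100 p-values the smoother
is unreliable and pi0 is fixed at 1.

### Rank-based GO association

For each contrast, genes with p below the threshold (default 0.05,
uniform across all contrasts so the gene sets are comparable in size) are
ranked by their log2 change, largest increase first. Each annotation term
whose membership within the list falls inside the size bounds is tested by
comparing in-term against out-of-term ranks with a rank-sum statistic:
exact enumeration of the null distribution for lists of up to 12 genes,
a normal approximation with tie and continuity corrections above that.
P-values are Benjamini–Hochberg-adjusted across the tested terms of one
contrast (each contrast is its own family), and reported as
`sign * -log10(p_fdr)` — positive when the term's genes crowd the
increased-expression end. The two-sided p is
`min(1, 2 min(lower tail, upper tail))`; the direction sign comes from the
in-term mean rank, with an exact tie breaking toward +1.

Numerical guards: `p_fdr` is floored at 1e-300 before the log so scores
stay finite (the cap is logged); average ranks make the statistic
invariant to the ordering of genes with tied effect sizes.

Default size bounds are 2 and (list size − 2): both rank groups need at
least two members for the comparison to mean anything. The annotation is
ancestor-expanded before testing — membership is closed under the term
parent relation, which is supplied as data (a parent table), not parsed
from an ontology release, so tests are exact and version-independent.

### Concordance, prediction, attenuation

Genes significant in **both** systems are intersected, carrying both log2
changes. On that common set the pipeline reports:

* the Pearson correlation of the two systems' log2 changes,
* the quadrant contingency table of effect signs (strict inequalities;
  exact-zero changes carry no sign and are excluded but counted),
* the two-sided Fisher exact p-value of the quadrant table, computed by
  hypergeometric enumeration in log space,
* prediction sensitivity `a/(a+b)` and specificity `d/(c+d)`, treating in
  vitro induction as a classifier of in vivo induction (that direction,
  never the reverse). An empty denominator yields a missing value, never
  zero,
* the same metrics restricted to one GO term (by default the
  inflammatory-response-like term), since the prediction claim is
  strongest on the shared inflammatory program.

The attenuation analysis asks, for every gene significantly induced by the
insult, whether the drug contrast pushes it back down (delta F−M < 0), and
summarizes the fraction reversed plus the correlation between the two
contrasts' effect sizes. The heatmap ordering sorts a gene set on the
insult effect, ties broken lexicographically, flagging genes also
significant in vitro.

## The synthetic-data generator

`simConfig()` encodes the study conditions; `simulateStudy()` draws from
them. The generator emulates:

* two experiments over one probeset scaffold (1–3 probesets per gene,
  uniform, with a fixed per-probeset log2 offset, sd 0.5, shared between
  systems as on a common array design),
* an in vivo arm with n = 3 per condition and an in vitro arm with 4
  matched control/stimulated pairs plus 2 unpaired control cultures
  (the unpaired cultures exercise the paired test's exclusion path),
* a shared inflammatory program (default 400 of 10,000 genes) induced in
  both systems with mean log2 effect 1.5 (per-gene effects vary uniformly
  within ±25% so ranked lists are informative), annotated to an
  inflammatory-response-like term inside a small, realistic term hierarchy
  plus random background terms,
* drug attenuation removing a fraction (default 0.8) of **every**
  insult-induced change — the drug acts on the insult response, not only
  on the annotated program,
* system-specific responders (default 300 per system, random sign, mean
  absolute effect 1.0) so concordance has something to discriminate
  against,
* log2-normal measurement noise (sd 0.25) around gene baselines drawn
  from N(7, 1.5) on the log2 scale, and a per-preparation random intercept
  (sd 0.25) shared by the two members of an in vitro pair, which is what
  makes the paired test genuinely more powerful in the synthetic world,
* intensity-dependent Absent calls: P(A) is a logistic function of the
  log2 intensity, 50% at log2 intensity 5 with unit slope; detected cells
  are Marginal with probability 0.05. Under these defaults roughly 10–25%
  of genes fail detection filtering, comparable to (somewhat milder than)
  real microarray experiments.

Everything is reproducible bit-for-bit from the seed.

What the generator does **not** model: probe-level behavior and its
summarization artifacts, between-array normalization drift, batch or
spatial effects, heavy-tailed or intensity-dependent variance, correlated
gene modules beyond the designed program. Passing tests therefore
demonstrate that the pipeline recovers known structure under a clean noise
model — not that any specific biological dataset will meet its
assumptions.

## Numerical and design choices

* **Welch at n = 3 is conservative.** With three samples per group the
  Satterthwaite approximation yields a true type-I rate near 0.033 at a
  nominal 0.05 (base R's `t.test` behaves identically). This is a property
  of the test, not of the implementation, so the null-calibration checks
  run the generator at 6 samples per condition and 6 pairs, where all
  three tests are essentially exact; the power analyses keep the realistic
  n = 3 design.
* **Truth-based recovery metrics condition on detectability.** Sensitivity
  and specificity against ground truth are computed over the genes that
  survive detection filtering in both systems: the concordance stage
  cannot classify a gene it never sees, and with a realistic detection
  model a fraction of the program is unobservable by construction.
* **Fisher's exact test** sums, in log space, hypergeometric probabilities
  at most (1 + 1e-7) times the observed table's, matching the standard
  two-sided convention; a zero margin returns p = 1 and is logged.
* **Problem sizes in the checks.** The test suite validates the exact
  statistics by full enumeration (all 2×2 tables with total ≤ 40; all
  rank-sum lists with total ≤ 10), calibrates type-I error on 5 × 2,000
  null genes, recovers pi0 = 0.8 from 20 × 10,000 mixture p-values, and
  runs the power, monotonicity (20 seeds per effect size), attenuation
  (20 seeds) and determinism analyses at the default 10,000-gene scale or
  at 1,000–2,000 genes where a smaller design suffices; each size is
  chosen so the property being checked is statistically stable.
* **Ambiguous probesets are rejected, not expanded.** Averaging many
  probesets into one gene is well defined; assigning one probeset to many
  genes is not, so such mapping rows are an input error.
* **Tie handling** is explicit everywhere: average ranks in the rank-sum
  statistic, lexicographic gene-id tie-breaks in sorted outputs, and a
  +1 direction sign on an exact mean-rank tie.

## Known limitations

* The rank-based GO association treats terms independently; no
  elim/weight-style decorrelation of nested terms is attempted, so
  ancestors of a true signal term score high too (visible in the examples:
  the designed term's ancestors trail it).
* The paired in vitro test requires explicit pair identifiers; it does not
  attempt to infer pairing from sample order.
* Storey's smoother estimate of pi0 is biased upward when the alternative
  fraction is small relative to noise; q-values remain valid but slightly
  conservative.
* The pipeline consumes MAS5-style output (intensities plus calls); it
  does not perform probe-level preprocessing or cross-array normalization.

## A worked run

```{r run, eval = FALSE}
st <- simulateStudy(simConfig(seed = 1))
pre <- preprocessExperiment(st$invivo, st$designInvivo, st$map)
preB <- preprocessExperiment(st$invitro, st$designInvitro, st$map)
ms  <- runWelchContrast(pre$genes,  st$designInvivo,  "S", "M")
lps <- runPairedContrast(preB$genes, st$designInvitro, "control", "LPS")
ann <- expandAnnotation(st$annotation)
concordanceAnalysis(ms, lps, 0.05, ann, restrictTerm = st$programTerm)
```

The same flow, file-based and with a manifest, is `runPipeline()`, and
`scripts/acceptance.R` (repository root) re-derives the headline numbers
from scratch for a given seed.
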