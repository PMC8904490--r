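---
title: "Copy-number-driven miRNA regulator inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-driven miRNA regulator inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmir)
```

## The scientific problem

Somatic copy-number aberrations (CNAs) in tumors recurrently amplify or
delete chromosomal regions that harbor miRNAs. A miRNA sitting inside such a
region is dosage-driven: its expression rises with amplification and falls
with deletion. If that miRNA regulates genes located *outside* the region
(trans genes), the aberration propagates across the genome through the
miRNA. `regmir` infers these miRNA→trans-gene interactions from paired
multi-omics profiles of a tumor cohort: segmented copy-number profiles, raw
gene-expression counts, miRNA expression (RPM), DNA-methylation beta values
and TF→target annotations.

The inference proceeds in four stages:

1. **Regions.** Recurrently aberrated regions are called from the segmented
   profiles (or ingested from an external caller's table), and every sample
   is labelled aberrated or non-aberrated per region by its overlap-weighted
   mean log2 ratio over the region, using strict thresholds of +0.1
   (amplification) and −0.1 (deletion).
2. **Differential expression.** Per region, genes are tested between the
   aberrated and non-aberrated groups with a TMM-normalized
   negative-binomial exact test; genes with |log2 fold change| ≥ 1 and
   BH-adjusted p < 0.05 are the region's DE genes.
3. **Predictor assembly.** DE genes overlapping the region are cis genes;
   the rest are trans genes. All expression-filtered miRNAs (RPM ≥ 0.01 in
   ≥ 30% of samples) inside the region are cis miRNAs — deliberately not
   subject to a DE filter, because regions contain few miRNAs and filtering
   them would cost sensitivity. Each trans gene with at least one cis miRNA
   gets a predictor matrix: cis-gene expression, cis-miRNA expression, its
   own gene-centric copy number, its own promoter methylation, and the
   expression of TFs annotated to target it.
4. **Stability-selection LASSO.** For each trans gene the L1 regression of
   its expression on the predictor matrix is repeated 100 times; each run
   re-draws 10-fold cross-validation folds and picks its own penalty. Cis
   miRNAs selected in at least 70 of the 100 runs become edges, signed by
   their mean coefficient. Negative signs match canonical miRNA-mediated
   repression; positive edges are kept too, since indirect regulation can be
   positively correlated.

## Models and estimators

### Region calling

The built-in caller is intentionally simple; a production analysis can (and
often should) supply externally computed regions. The genome is tiled in
fixed bins (default 50 kb). Per sample and bin, the overlap-weighted mean
log2 ratio $x_{sb}$ is computed; per direction the bin score is

$$G(b) = \sum_s \max(0,\, x_{sb} - 0.1) \quad\text{(amp)};\qquad
  G(b) = \sum_s \max(0,\, -0.1 - x_{sb}) \quad\text{(del)}.$$

The null distribution of $G$ is built by cyclically shifting each sample's
bin profile within each chromosome (default 200 shifts) and pooling the
permuted scores across bins and permutations. Bin-level empirical p-values
are BH-adjusted; contiguous significant bins (q ≤ 0.25, at least 2 bins)
merge into a region. Amplifications and deletions are scored independently,
so one locus can yield both. Bins covered in fewer than half the samples are
skipped. Samples with no segment over a region are non-aberrated (logged),
and values exactly at ±0.1 do not count as aberrated — the thresholds are
strict inequalities.

### Differential expression

The count model is the classic exact-test stack. TMM factors are computed
against the sample whose upper quartile is closest to the cohort mean, with
30% trimming of log-ratios, 5% trimming of log-abundances and
inverse-variance weights. A single common NB dispersion is estimated by
conditional maximum likelihood on pseudo-counts equalized to the geometric
mean effective library size, maximized on a log grid refined with
`stats::optimize()`; Poisson-like data hit the boundary and report 0. The
per-gene test conditions on the (rounded) total pseudo-count and computes
the two-sided probability of splits at most as likely as the observed one
under the NB (binomial when the dispersion is 0). logFC uses a prior count
of 0.5 per group mean. BH adjustment is applied within each region, the
unit at which DE lists feed the next stage. Numerical identity with any
particular reference implementation is *not* the contract — statistical
behavior is: the suite checks type-I error calibration, dispersion recovery
against simulated truth and exact label-swap antisymmetry, and cross-checks
the TMM factors against an independent implementation.

A distribution-free Wilcoxon mode (`de_config(method = "wilcoxon")`) is
available as a robustness check; its exact small-sample p-values equal full
permutation enumeration.

### Stability-selection LASSO

For a predictor matrix $X$ (standardized per column: mean 0, mean square 1)
and centered response $y$, the solver minimizes
$\tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$ by
cyclic coordinate descent with warm starts along a descending grid of 100
log-spaced penalties from $\lambda_{\max} = \max_j |x_j^\top y|/n$ down to
$10^{-3}\lambda_{\max}$. Coefficients at $\lambda \ge \lambda_{\max}$ are
exact zeros; convergence is declared when the largest coefficient change in
a sweep is below $10^{-7}$, and KKT residuals of every refit are tracked.

Each of the 100 runs re-draws the CV folds from its own seed; nothing else
varies, so the full-data path is computed once and a run just reads the
coefficients at its own $\lambda^*$. The penalty rule deserves a note. We
read "the simplest model with the minimum cross-validation error" as the
one-standard-error rule: the largest $\lambda$ whose CV error is within one
standard error of the minimum (`lambda_rule = "one_se"`, the default). The
literal alternative — the largest $\lambda$ attaining the exact minimum
(`lambda_rule = "min"`) — is implemented and available, but in our
experiments it stably selects predictors whose fixed finite-sample partial
correlations sit just above the noise floor: because only the folds are
re-drawn, such predictors are selected in essentially every run and the
70-of-100 consensus cannot remove them. The one-SE rule restores the
sparsity the consensus semantics assume.

Seeds for each (region, trans gene) job derive from the global seed and the
unit's identifiers, never from scheduling order, so results are independent
of execution order and bytewise reproducible.

### Two-phase residual mode

With `two_phase = TRUE`, transcription-level covariates (cis genes, copy
number, methylation, TFs) are stability-selected first; the consensus is
refit by least squares and the residual becomes the response of a second,
miRNA-only stability selection. When phase 1 selects nothing the residual
falls back to the centered response. This mode separates transcriptional
from post-transcriptional variance but, with a latent region-status factor
measured only through noisy covariates, the unshrunk OLS residual can
redistribute status signal across miRNAs; it is therefore an option, not
the default.

### Evaluation statistics

Ground-truth miRNA→gene pairs are expanded through TF targets: if a
validated target of a miRNA is a TF, the TF's validated targets join the
truth set as indirect targets. Per-miRNA target enrichment uses the
upper-tail hypergeometric test within an explicit gene universe; a miRNA is
*eligible* only if at least one of its *computed* targets is a known target
(a miRNA whose known targets were all missed is not eligible — the literal
reading; the alternative is a flag away in user code since the universe and
truth are explicit inputs). Oncogenic-miRNA enrichment is a two-sided
Fisher exact test against the background of all miRNAs that entered the
selection step. Method comparison restricts to miRNAs eligible under both
methods and compares counts of significant miRNAs, with `not_comparable`
verdicts for empty overlaps. All universes are explicit arguments — they
are never inferred silently, because each test has a different natural
universe.

## The synthetic cohort

`generate_cohort()` produces a full multi-omics cohort with known truth so
that every stage and every statistic can be tested without external data.
The default configuration: 150 samples, 300 genes, 30 miRNAs, three 1 Mb
regions (two amplifications, one deletion) on 10 Mb chromosomes, 60%
recurrence, and 5 planted miRNA→trans-gene edges of standardized effect 0.9
with negative sign.

Choices a reader may want to audit:

* **Aberration amplitude ±1.3.** Carriers' segments over a region are
  centred at log2 ±1.3 (strong focal events, ~4.9 copies for the gain).
  The amplitude must exceed the DE filter's own bar: with a one-to-one
  dosage→expression slope, cis genes shift by the amplitude itself, so an
  amplitude materially above 1 is required for the planted cis genes to
  clear |logFC| ≥ 1 — at, say, 0.8 the planted cis-gene layer is invisible
  to the pipeline's DE step and the fixture stops being a test of anything.
* **miRNA noise sd 0.7 (log2).** Tumor miRNA expression varies well beyond
  copy number; this also keeps same-region cis miRNAs from being
  near-collinear through their shared carrier set, which no selection
  threshold could disentangle.
* **Counts.** Gene counts are NB with dispersion 0.1 around log2 means
  composed of dosage, methylation (slope −2 on beta, on a disjoint gene
  subset), TF (0.4 per standardized TF expression) and edge effects; miRNA
  expression is generated directly on the RPM scale, the scale on which the
  pipeline regresses. Mean library size is 15,000 over 300 genes — per-gene
  coverage comparable to RNA-seq while keeping the exact test's
  enumeration cheap.
* **Decoys.** Each region plants one decoy trans gene driven by the
  realized (library-normalized) expression of one of its cis genes, plus
  one non-edge cis miRNA. Decoys are differentially expressed through the
  region but owe nothing to any miRNA, so edge selection has something it
  must refuse; drivers are computed on the observable normalized scale
  precisely so that the cis-gene predictor is a faithful mediator — a
  raw-scale driver would hide the library-size component from every
  predictor and manufacture unremovable false positives.
* **True edges** subtract `edge_effect` times the standardized observed
  miRNA expression from the target's log2 mean, so the planted coefficient
  is negative on exactly the scale the LASSO sees.

What passing on this cohort does *not* show: robustness to subclonal CNAs,
arm-level events, batch effects, expression outliers, probe-level
methylation noise, or annotation errors — none of which are simulated.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on the
default 150 × 300 cohort (seconds per run on one core) and the DE
calibration on 2,000 genes at 20 vs 20 samples; these sizes were chosen so
that planted structure is comfortably recoverable while whole-suite runs
stay interactive. Every random draw descends from explicit seeds; two runs
with the same configuration and seed produce byte-identical outputs, and
output files carry only the tool version and config hash (no timestamps) so
that reruns can be compared with `diff`.

## Known limitations

* The region caller is a deliberately simple recurrence scorer: no
  marker-level scoring, arm-level correction, peel-off of overlapping
  peaks, or confidence-interval boundary estimation. External region tables
  are first-class input for serious use.
* Only a common NB dispersion is estimated (no tagwise/trended shrinkage),
  which is anti-conservative for genes with atypical dispersion.
* The LASSO consensus inherits the usual limits of stability selection with
  fold-only resampling: a systematic confounder that no predictor mediates
  cannot be rejected by re-drawing folds.
* Methylation aggregation supports promoter-window (450K-style) and
  all-probe (27K-style) averaging; strand-aware windows default to
  TSS −2000/+500 bp and are configurable.
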