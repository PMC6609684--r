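---
title: "Reproducing gastric cancer molecular subtypes across expression platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducing gastric cancer molecular subtypes across expression platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsubtypes)
```

## The model

The ACRG classification assigns each gastric tumor one of four labels —
EMT, MSI, MSS/TP53+, MSS/TP53− — from three signature scores. A signature
score is deliberately simple: the unweighted mean of log2 expression over
the signature's member genes. Simplicity is what makes the score portable
across platforms; the entire cross-platform problem is then concentrated in
two places: whether each *gene* reads out comparably on both platforms, and
where the *cutoffs* sit on the new platform's score scale.

The pipeline treats those two places explicitly:

* **Per-gene concordance filtering.** For every EMT and MSI signature gene,
  the Pearson correlation of its expression across the shared samples of
  the two platforms is computed; genes with r below 0.4 are removed (the
  boundary value is retained). Filtering is not applied to the TP53
  signature: it has only two genes (CDKN1A and MDM2 — transcriptional
  targets of active p53), and removing one would change the meaning of the
  score rather than clean it.
* **Cutoff handling.** The EMT (5.6) and MSI (5.5) cutoffs are fixed
  operating points on the mean-log2 score scale. The TP53 cutoff is
  re-derived per cohort: among the samples not already called EMT or MSI,
  the ROC of the TP53 score against TP53 somatic mutation status is swept
  and the threshold maximizing Youden's J = sensitivity + specificity − 1
  is used (the original cross-platform study obtained 6.19 this way, which
  this package keeps as the fallback when no mutation data are available).

Classification is step-wise with strict inequalities: EMT if the EMT score
exceeds its cutoff; otherwise MSI by the MSI score; otherwise the TP53
score splits MSS/TP53+ (above) from MSS/TP53− (at or below). A sample
exceeding both the EMT and MSI cutoffs is called EMT: the scheme is
sequential and the EMT step is applied first. The source description does
not state what should happen in that double-exceedance case, so the
precedence is a documented package decision (configurable in
`classify_subtypes()` via the cutoffs, and reported via a message whenever
it actually triggers).

Performance against a gold-standard labeling is summarized by the confusion
matrix, overall accuracy with an exact one-sided binomial test against the
no-information rate (the largest gold class's frequency — at n = 50 the
exact tail is used rather than a normal approximation), Cohen's kappa,
one-vs-rest sensitivity and specificity, score-vs-subtype ROC/AUC with a
two-sided Mann-Whitney test, Spearman associations between signature scores
and the leading principal components (computed on gene-centered, unscaled
log2 values; PC signs are arbitrary and only |rho| is interpretable), and
Kaplan-Meier curves with a k-group log-rank test across the four called
subtypes.

## The minimal EMT panel

Because the EMT subtype drives treatment decisions, the package also
derives a minimal gene panel (default 10 genes) for EMT discrimination:
genes are ranked by Pearson correlation with the EMT target, the top genes
are kept, and an ordinary least-squares regression of the 0/1 EMT indicator
on the panel's log2 expression provides the prediction score, with the
decision cutoff again chosen by Youden's J.

Two design points were genuinely open and are resolved as follows:

* **Correlation target.** "Correlation with EMT" can mean correlation with
  the continuous EMT signature score or with the binary subtype indicator.
  The default is the binary indicator (a point-biserial correlation),
  because the panel's job is subtype discrimination and its evaluation is
  against subtype membership; the continuous target can be supplied to
  `rank_genes_by_emt_correlation()` instead.
* **Threshold vs size.** A correlation floor (0.65) and a fixed panel size
  (10) can conflict — a 10-gene panel whose observed correlations range
  below the floor is internally inconsistent with a hard threshold.
  `select_panel()` therefore selects exactly `size` genes by rank and
  treats the floor as a reported diagnostic, warning when fewer than `size`
  genes reach it.

The model family is a linear probability model (OLS on the 0/1 indicator),
matching the method's plain "linear regression" description; logistic
regression is deliberately not substituted, since the score only feeds a
thresholded decision and the ROC sweep is invariant to any monotone
rescaling of the score.

## What the synthetic cohorts emulate

`simulate_cohort()` generates paired-platform cohorts with the structure
the analysis assumes, so that every stage is testable without external
data:

* Each gene has a log2 baseline drawn from N(5, 1.2²). The baseline mean of
  5 places signature scores on the scale of the published cutoffs
  (5.5–5.6), so the fixed EMT/MSI operating points are meaningful on
  simulated data.
* Shared biological variation (SD 1.0 on the log2 scale) plus
  platform-specific measurement noise (SD 0.5 each). A configurable
  fraction of genes (default 0.6) is *concordant* — both platforms read the
  shared signal, giving an expected cross-platform r of about 0.8 at these
  defaults; the rest are *discordant* — the target platform reads an
  independent draw, giving expected r ≈ 0 and, importantly, no subtype
  signal on the target platform. The planted class of every gene is
  recorded in the cohort's `truth` table.
* EMT and MSI signature genes (sizes 118 and 120, the sizes of the
  signatures being filtered) are shifted +2 log2 units in samples of their
  subtype; CDKN1A/MDM2 are shifted +2 in TP53 wild-type samples, the
  direction consistent with calling high TP53 scores "MSS/TP53+".
* The target platform is log-normal (TPM = 2^latent − 1, floored at 0),
  reproducing the positively skewed, wide-ranged RNA-seq distributions seen
  in archival tissue, with dropout applied as zeros to genes in the lowest
  baseline quartile (rate 0.1) — producing the zero-vs-robust-signal pairs
  characteristic of degraded FFPE RNA against fresh-frozen arrays.
* Survival is exponential with subtype hazards 0.4 (EMT), 0.2 (both MSS),
  0.1 (MSI) per unit time and independent exponential censoring tuned so
  the expected censored fraction is 0.3 in every subtype. This plants the
  observed prognostic ordering (MSI best, EMT worst).
* Default subtype proportions are 0.2/0.2/0.3/0.3
  (EMT/MSI/MSS-TP53+/MSS-TP53−); the real 50-sample cohort's composition
  was never published, so the proportions are a simulation parameter, not a
  claim about the cohort.

What the generator does **not** emulate: probe-level microarray structure
(probe collapsing is exercised on synthetic probe maps in its own tests),
batch effects, library-size renormalization to exactly 10⁶ (scores use
log2 values only, so rank structure is unaffected), count-level noise (the
observable being modeled is zero log2 expression, not read counts), and
correlated gene-gene structure beyond the planted subtype axes. Passing
tests on these cohorts therefore demonstrate that the *pipeline machinery*
is correct and that the method recovers planted structure under its own
assumptions — not that any particular real cohort will reach the same
accuracy.

## Numerical choices

* Log2 pseudocount 1, so TPM 0 maps to log2 value 0 and dropout zeros stay
  visible; the same pseudocount is applied to (already positive) microarray
  intensities for uniformity.
* The low-expression filter removes genes with mean TPM strictly below 2; a
  mean of exactly 2 is retained.
* The concordance filter keeps r ≥ 0.4. The source text states the removal
  boundary both as "≤ 0.4" (abstract) and "lower than 0.4" (results); the
  results wording is implemented and the threshold is configurable.
* ROC thresholds are the midpoints between consecutive distinct scores plus
  ∓∞ sentinels; "positive" means score strictly greater than the
  threshold. The trapezoid AUC then equals the Mann-Whitney identity
  U/(n₁n₀) with ties credited ½. Youden ties resolve to the smallest
  threshold, compared within a 10⁻⁹ tolerance so that floating-point noise
  cannot skip an exactly tied smaller threshold. An AUC below 0.5 is
  reported with its direction rather than silently flipped.
* Probe collapsing selects the whole row of the probe with maximal mean
  signal (ties: lexicographically smallest probe id), preserving
  within-probe covariance; a per-sample maximum is the other reading of
  "maximum signal value" but would splice rows from different probes.
* Degenerate inputs are first-class: constant vectors yield missing
  correlations (excluded from medians, flagged in concordance tables), a
  single mutation class aborts calibration with the fixed fallback cutoff
  suggested, one-sided survival splits return the estimator with a missing
  log-rank result, and a class with no gold members reports missing
  sensitivity while specificity stays defined.

## Problem sizes in the test suite

The statistical guarantees are verified on simulated cohorts of 200 samples
(about 590 genes) over 20 seeds for subtype recovery and panel derivation,
100-sample cohorts for concordance properties, 500-replicate null
simulations for the type-I error of the log-rank and Mann-Whitney tests,
and 1,000 random micro-instances per operation for the brute-force oracle
equivalences (ROC/Youden, kappa, probe collapsing, TPM filtering). These
sizes keep the full suite under a few minutes while leaving Monte-Carlo
margins well clear of the asserted bounds.

## Known limitations

* The published headline numbers (66% accuracy, kappa 0.55, score
  correlations 0.66→0.73 and 0.19→0.70, 10-gene AUC 0.92) were computed on
  an archival cohort whose RNA-seq profiles are not publicly deposited;
  they serve as documented reference values, not as reproduction targets.
  On synthetic cohorts the pipeline scores higher — planted effects are
  cleaner than FFPE biology.
* The per-gene concordance filter needs paired samples on both platforms;
  applying the classifier to a new cohort without paired data means reusing
  a previously derived filtered signature and cutoffs.
* The TP53 split rests on two genes; when one of them is poorly measured on
  the target platform the MSS split degrades, and the calibration warning
  (maximal J < 0.2) is the designed signal of that failure mode.
* The 10-gene panel is re-derived from data on every run; the package never
  hard-codes a gene list, because the original panel's identities were not
  published.
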