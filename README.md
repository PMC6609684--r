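# gcsubtypes

Cross-platform reproduction of the four ACRG molecular subtypes of gastric
adenocarcinoma — **MSS/TP53+**, **MSS/TP53−**, **MSI** and **EMT** — from
gene-level expression profiles measured on a second platform.

## The problem

The ACRG expression subtypes of gastric cancer carry real clinical weight:
the EMT (mesenchymal-like) subtype has the worst prognosis and responds
poorly to checkpoint blockade, while MSI tumors respond well. The subtypes
were defined on fresh-frozen microarray profiles, but clinical screening has
to work on archival FFPE tissue profiled by targeted RNA-seq — a platform
whose degraded RNA produces positively skewed TPM distributions, expression
dropouts, and gene-specific cross-platform correlations ranging from ~0 to
high. `gcsubtypes` implements the harmonization and classification pipeline
that bridges the two platforms, for computational oncologists who need to
port an expression classifier across platforms and quantify how well it
survives the trip.

## The method

For a sample *j* and a signature *G* (EMT, MSI, or the two-gene TP53
signature {CDKN1A, MDM2}), the signature score is the unweighted mean of
log2 expression,

```
score_G(j) = (1/|G|) * sum over g in G of log2(x_gj + 1)
```

The pipeline:

1. **Harmonize.** Collapse microarray probes to genes (probe with maximal
   mean signal), drop target-platform genes with mean TPM < 2, log2(+1)
   transform both platforms, intersect on common genes and samples.
2. **Filter signature genes by concordance.** Compute each signature gene's
   Pearson correlation *r* across platforms; remove EMT/MSI signature genes
   with *r* < 0.4. The two-gene TP53 signature is not filtered.
3. **Classify step-wise.** EMT if EMT score > 5.6; else MSI if MSI score
   > 5.5; else MSS/TP53+ if the TP53 score exceeds a cutoff calibrated per
   cohort at the maximum of Youden's *J* = sensitivity + specificity − 1 on
   the ROC of the TP53 score against TP53 mutation status (computed on the
   samples not already called EMT/MSI); else MSS/TP53−. All comparisons are
   strict.
4. **Evaluate.** Confusion matrix vs the gold subtype, overall accuracy with
   an exact binomial no-information-rate test, Cohen's kappa, one-vs-rest
   sensitivity/specificity, score-vs-subtype ROC + Mann-Whitney tests,
   PCA–signature Spearman associations, and Kaplan–Meier/log-rank survival
   by called subtype.
5. **Minify.** Derive a 10-gene EMT panel: rank genes by (point-biserial)
   correlation with the EMT indicator, keep the top genes (correlation floor
   0.65 reported as a diagnostic), fit ordinary least squares of the 0/1
   indicator on the panel's log2 expression, and pick the score cutoff by
   Youden's *J*.

A first-class synthetic cohort generator (`simulate_cohort()`) plants the
statistical structure this pipeline assumes — four subtypes, signature-gene
up-shifts, concordant/discordant cross-platform gene classes, targeted TPM
dropout, CDKN1A/MDM2 coupling to TP53 status, and subtype-ordered
exponential survival — so every stage is testable without external data.

## Worked example

```r
library(gcsubtypes)

cohort <- simulate_cohort(simulation_config(seed = 7))   # 50 samples, paired platforms
res <- run_subtype_pipeline(
  cohort$reference, cohort$target, cohort$signatures, cohort$clinical
)
res
#> # Cross-platform subtype reproduction
#> TP53 cutoff: 5.009 (calibrated)
#>
#>       EMT       MSI MSS/TP53- MSS/TP53+
#>        13         8        11        18
#> # Classification performance on 50 samples
#> accuracy 0.920 (NIR 0.300, exact binomial p = 5.08e-20), kappa 0.892
#>            predicted
#> gold        EMT MSI MSS/TP53- MSS/TP53+
#>   EMT        13   0         0         0
#>   MSI         0   8         0         0
#>   MSS/TP53-   0   0        11         4
#>   MSS/TP53+   0   0         0        14
#> # A tibble: 4 × 4
#>   class     n_gold sensitivity specificity
#>   <chr>      <int>       <dbl>       <dbl>
#> 1 EMT           13       1           1
#> 2 MSI            8       1           1
#> 3 MSS/TP53-     15       0.733       1
#> 4 MSS/TP53+     14       1           0.889
```

The TP53 cutoff (5.009 here) is re-derived per cohort from the ROC of the
TP53 score against mutation status; the confusion matrix shows the step-wise
rule recovering the planted subtypes, with the residual errors concentrated
in the two-gene MSS/TP53 split — the hardest boundary, exactly as on real
cohorts. Correlation filtering improves the cross-platform agreement of the
signature scores:

```r
subset(res$score_concordance, signature %in% c("EMT", "MSI"))
#> # A tibble: 2 × 5
#>   signature pearson_before n_genes_before pearson_after n_genes_after
#>   <chr>              <dbl>          <int>         <dbl>         <int>
#> 1 EMT                0.988            118         0.994            70
#> 2 MSI                0.963            120         0.992            72

glance(res$survival)     # log-rank across the four called subtypes
#> # A tibble: 1 × 5
#>       n n_events statistic    df p_value
#>   <int>    <int>     <dbl> <int>   <dbl>
#> 1    50       34      1.18     3   0.757
```

Results follow broom conventions (`tidy()`, `glance()`) and ggplot2
(`autoplot()` on ROC curves and survival fits, `plot_score_scatter()` for
the score-space view of the classifier).

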