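# emtime

Pan-cancer EMT scoring and tumor immune microenvironment (TIME) profiling
for bulk expression cohorts.

Epithelial–mesenchymal transition (EMT) — the shift of tumor cells from an
epithelial to a motile mesenchymal state — reshapes the immune milieu of a
tumor: mesenchymal tumors tend to accumulate tumor-associated macrophages,
overexpress immune checkpoints, and secrete immunosuppressive cytokines.
`emtime` implements that analysis as a tested, reusable pipeline for anyone
working with per-gene z-scored expression matrices (e.g. GDAC
Firehose-style TCGA tables), xCell-style immune enrichment scores and
clinical time-to-event tables.

## The model

Each sample gets a continuous EMT score from 16 canonical markers:

```
EMT(s) = mean( z[mesenchymal genes, s] ) − mean( z[epithelial genes, s] )
```

with mesenchymal = {VIM, CDH2, FOXC2, SNAI1, SNAI2, TWIST1, GSC, FN1,
ITGB6, MMP2, MMP3, MMP9, SOX10} and epithelial = {CDH1, DSP, TJP1}.
Within each cohort, the top score quartile is EMT-high ("mesenchymal"),
the bottom quartile EMT-low ("epithelial"), the middle half
EMT-intermediate. Every TIME marker — 17 immune-cell enrichment scores,
17 checkpoint genes, 17 cytokine genes, 8 gene signatures — is then
contrasted between groups: median(high) − median(low), a two-sample
Kolmogorov–Smirnov test (high vs low), one-way ANOVA (three groups), and
the Spearman correlation with the continuous score. Across cohorts, the
package runs PCA on per-group median profiles, computes conditional
probabilities of high marker expression given EMT group, classifies cancer
types by silhouette-selected K-means on high-minus-low delta profiles, and
compares OS/PFI between EMT groups with Kaplan–Meier curves and log-rank
tests. A seeded synthetic-cohort generator with planted ground truth makes
every stage testable without any download.

## Worked example

```r
library(emtime)

co     <- generate_cohort(simulation_config(n_samples = 400, seed = 1))
scores <- compute_emt_score(co$expression)
groups <- stratify_by_emt(scores)

summarize_distribution(scores)
#>   cohort_id   n     median  quartile1 quartile3      iqr
#> 1      SIM1 400 -0.0763278 -0.8299106 0.9623608 1.792271
table(groups$group)
#>          low intermediate         high
#>          100          200          100

sig  <- score_signatures(co$expression)
tt   <- assemble_time_table(co$enrichment, co$expression, sig_scores = sig)
land <- build_landscape(tt, groups, scores)
head(land[order(-land$delta_median),
          c("marker", "category", "delta_median", "ks_p", "ks_band", "corr_rho")], 5)
#>          marker    category delta_median         ks_p ks_band  corr_rho
#>  Macrophages M2 immune_cell     1.750438 1.587524e-24     *** 0.6273997
#>         TNFRSF4  checkpoint     1.726997 1.923610e-29     *** 0.6191495
#>           TGFB1    cytokine     1.677326 4.962294e-23     *** 0.6166340
#>            IL10    cytokine     1.644292 2.485563e-30     *** 0.6390381
#>             tam   signature     1.632263 1.428736e-51     *** 0.8675274

sv <- survival_by_emt_group(co$clinical, groups, "os")
sv$logrank_high_vs_low[c("chi2", "p_value")]
#> $chi2
#> [1] 36.00317
#> $p_value
#> [1] 1.977755e-09
```

The landscape rows read: in this simulated cohort, M2 macrophage
enrichment is 1.75 units higher at the median in EMT-high than in EMT-low
samples, the high/low distributions differ at p ≈ 10⁻²⁴, and the marker
correlates at ρ = 0.63 with the continuous EMT score — the pattern the
pipeline is designed to surface. The log-rank test shows the planted
survival disadvantage of the mesenchymal group (hazard ratio 2).

A full multi-cohort run (scores → contrasts → PCA/K-means → survival, all
tables plus a checksummed manifest) is one call:

```r
cfg <- run_config("out_dir", seed = 1,
                  simulate = list(n_cohorts = 22, n_samples = 400))
run_pipeline(cfg)
```

or from a shell via the thin wrapper
`Rscript inst/cli/emtime.R run-all --out out_dir --seed 1` (subcommands:
`simulate`, `score`, `contrast`, `cluster`, `survive`, `run-all`; exit
codes 0/2/3 for success / validation error / stage failure). Real cohorts
are supplied as per-cohort TSV paths through `run_config(inputs = ...)`.

## Documentation

The methods vignette (`vignettes/emtime-methods.Rmd`) describes the score,
the stratification tie rule, the statistical conventions (quantile type,
exact-vs-asymptotic KS, PCA standardization, the silhouette policy), what
the synthetic generator does and does not emulate, and known limitations.
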