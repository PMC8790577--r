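---
title: "EMT scoring and immune-microenvironment profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT scoring and immune-microenvironment profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtime)
```

## The scientific problem

Epithelial–mesenchymal transition (EMT) is the program by which polarized
epithelial tumor cells acquire a motile, mesenchymal phenotype; it is a
central driver of invasion, metastasis and immune escape. Tumors with a
strongly mesenchymal expression state tend to carry a markedly different
tumor immune microenvironment (TIME) — more tumor-associated macrophages,
higher checkpoint-molecule expression, more immunosuppressive cytokines —
than epithelial tumors of the same cancer type. `emtime` packages that
analysis end-to-end for bulk expression cohorts: score each sample's EMT
state, cut each cohort into EMT-defined groups, and test every TIME marker
for association with those groups.

## The EMT score and quartile stratification

The score operates on per-gene z-scored expression (each gene standardized
to mean 0, SD 1 across a cohort's samples, the form distributed by GDAC
Firehose). For a sample $s$,

$$\mathrm{EMT}(s) \;=\; \frac{1}{|M|}\sum_{g \in M} z_{gs}
\;-\; \frac{1}{|E|}\sum_{g \in E} z_{gs},$$

where $M$ is the mesenchymal marker list (VIM, CDH2, FOXC2, SNAI1, SNAI2,
TWIST1, GSC, FN1, ITGB6, MMP2, MMP3, MMP9, SOX10) and $E$ the epithelial
list (CDH1, DSP, TJP1) — 16 canonical markers in total. Positive scores
indicate mesenchymal character. Missing values are excluded pairwise: each
sample's means run over the panel genes it actually has; a sample with no
usable gene on one side gets a missing score and is excluded from
stratification with a warning. We considered dropping such samples
entirely, but silent loss of rows is the kind of behavior that makes
cross-cohort counts irreproducible.

Cohorts are eligible for analysis only when they have more than 100 samples
and all epithelial markers present; a matrix lacking CDH1, for instance, is
rejected with an explicit reason rather than scored on a 2-gene epithelial
side. Both thresholds and the required-gene set are arguments of
`check_cohort_eligibility()`.

Each cohort is then cut at its within-cohort score quartiles: top quartile
EMT-high ("mesenchymal"), bottom quartile EMT-low ("epithelial"), middle
half EMT-intermediate. Two numerical conventions are fixed here because the
quartile wording alone does not determine behavior under ties:

* **Quantiles** are linear-interpolation ("type 7") quantiles throughout —
  both the reported group boundaries and the distribution summaries
  (`summarize_distribution()`'s median/IQR).
* **Group membership** uses a deterministic rank rule rather than a
  threshold comparison: samples are ranked by (score, stable input
  position); the lowest $\lfloor n/4 \rfloor$ ranks are low and the ranks
  above $\lceil 3n/4 \rceil$ are high. With distinct scores this coincides
  with the quantile cut (1,000 distinct scores give exactly 250 high), and
  with ties it still produces exact, reproducible group sizes instead of
  letting a tied boundary value inflate one group.

## The TIME marker table

Markers from four sources are joined into one markers-by-samples table over
the shared sample set:

* **Immune cells** — 17 cell types' precomputed per-sample enrichment
  scores (an xCell-style table). These scores are consumed as an input;
  the package does not reimplement the enrichment algorithm.
* **Checkpoints** — 17 checkpoint molecules (PD1, PD-L1, PD-L2, CTLA4,
  LAG3, KIR, TIM3, VISTA, NOX2, SIGLEC5, SIGLEC7, SIGLEC15, FASLG, ICOS,
  GITR, TNFRSF4, TNFRSF9), each represented by its gene's z-score row.
  Common names are resolved to HGNC symbols through an editable alias table
  (`default_marker_aliases()`; e.g. PD1 → PDCD1, TIM3 → HAVCR2); gene
  symbols are otherwise matched case-sensitively with no alias inference.
* **Cytokines** — 17 cytokine genes (IFNA1 … STAT6), likewise z-score rows.
* **Signatures** — per-sample scores for eight gene signatures
  (IFN-gamma 6-gene, inflammatory 13-gene, exhausted CD8 9- and 3-gene,
  activated stroma, hypoxia, cytolytic activity, TAM).

A signature's score is the unweighted mean z over its member genes present
in the matrix. The mean-z rule was chosen because it is the minimal
aggregation consistent with the EMT score's own mean-difference form and is
exactly linear, which makes every downstream identity testable (a 1-gene
signature equals that gene's row; mesenchymal-signature minus
epithelial-signature equals the EMT score). Sample-permutation methods such
as ssGSEA are deliberately out of scope. The shipped signature memberships
are package-curated versions of widely used published signatures of those
names; when exact membership matters, supply your own GMT file — every
entry point accepts one.

A marker whose gene is absent from a cohort's matrix is kept as an
all-missing row with a warning; markers are never silently dropped, so the
marker-by-cohort landscape always has a complete, aligned row set.

## Group contrasts

For every marker in every cohort, `build_landscape()` computes:

* **delta median** — median(EMT-high) − median(EMT-low), the quantity
  behind median-difference landscape heatmaps;
* **Kolmogorov–Smirnov test** of high vs low:
  $D = \sup_t |\hat F_{\text{high}}(t) - \hat F_{\text{low}}(t)|$, with an
  exact two-sided p-value when $n_\text{high} n_\text{low} \le 10{,}000$
  and there are no ties, asymptotic otherwise;
* **one-way ANOVA** across the three groups (classic equal-variance F,
  df $(k-1, N-k)$);
* **Spearman correlation** of the marker with the continuous EMT score,
  with the asymptotic t-approximation p-value. Rank correlation is the
  default because enrichment scores are heavy-tailed and the EMT–marker
  relationship of interest is monotone rather than linear; Pearson is
  available by flag.

P-values are reported raw, with the conventional significance bands
(\*\*\* $p<0.001$, \*\* $p<0.01$, \* $p<0.05$, NS); Benjamini–Hochberg or
any other correction can be applied to the exported tables by the user.
Markers are compared on their native scales — no re-standardization before
testing, since all four test statistics are invariant to per-marker
monotone (KS, Spearman) or affine (ANOVA, delta sign) transforms.

## PCA, conditional probabilities, K-means

Two profile matrices summarize the landscape across cohorts: the
(cohort × group)-by-marker matrix of per-group medians, and the
cohort-by-marker matrix of high-minus-low delta medians. PCA (via SVD on
the column-centered matrix) is run with columns scaled to unit variance by
default, because the markers mix enrichment scores, z-scores and signature
means whose variances are not comparable; raw-covariance PCA is available
by flag. A marker's contribution to a component is its squared-loading
share (each component's contributions sum to 100%), and the top
contributors to PC1 are ranked by that share with alphabetical
tie-breaking.

"High expression" of a marker, for the conditional-probability analysis
P(high | EMT group), means at or above the pooled within-cohort median by
default (any pooled quantile can be configured). The pooled median makes
the overall P(high) exactly one half and the law of total probability holds
by exact counting, which the tests assert to $10^{-12}$.

Cancers are classified on their delta profiles by Lloyd's K-means
(Euclidean, best of 50 random restarts, default seed 17) for each K in
2–8, and the reported K maximizes the mean silhouette width (ties resolve
to the smaller K). Restarts that produce an empty cluster are redrawn.

## Survival

Overall survival and progression-free interval are analyzed per cohort with
the Kaplan–Meier product-limit estimator and the standard unweighted
log-rank test (Mantel–Haenszel hypergeometric variance with ties), both
three-group and pairwise high-vs-low. Records missing a time or event are
dropped per endpoint, not per subject. "PFS" and "PFI" naming varies in the
literature; the package treats them as one progression endpoint labelled
PFI.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* a latent EMT axis $a_s \sim N(0, \sigma_\text{axis}^2)$ per sample
  (default SD 1);
* mesenchymal panel genes $z = +a_s + \varepsilon$, epithelial genes
  $z = -a_s + \varepsilon$, every TIME marker
  $\beta\, a_s + \varepsilon$ with configurable coupling $\beta$
  (positive, negative or null per marker), noise
  $\varepsilon \sim N(0, \sigma_\text{noise}^2)$ (default SD 1, i.e. noise
  as large as signal);
* gene rows re-standardized to mean 0, SD 1, matching the z-scored input
  contract;
* enrichment scores passed through a softplus to keep them non-negative;
* exponential survival with hazard $\lambda_0 \cdot \mathrm{HR}^{g}$,
  $g = 0, \tfrac12, 1$ for low/intermediate/high — linked to the discrete
  stratified group, not the latent axis, because the analysis's survival
  contrasts are group-based (default $\lambda_0 = 10^{-3}$ per day,
  HR = 2, 30% censoring; censored subjects report a uniform fraction of
  their event time). The PFI endpoint uses a 1.5× baseline hazard.

Defaults are sized at 400 samples per cohort and 22 cohorts, the scale of a
mid-sized solid-tumor cohort collection. `generate_multicohort()` plants
cluster structure by drawing cohorts from archetypes with distinct coupling
vectors (default: an "inhibitory" archetype with the standard couplings and
a sign-flipped contrast archetype), recording membership as ground truth.

The generator is linear-Gaussian by design — the minimal structure under
which monotone EMT–marker couplings are well-defined and recoverable. It
does **not** emulate gene–gene correlation beyond the shared axis, compositional
constraints among immune-cell fractions, batch effects, or non-exponential
hazards. Passing the recovery tests therefore demonstrates that the
pipeline's statistics detect what they claim to detect under their own
assumptions, not that real TCGA cohorts satisfy those assumptions.

## Calibration facts worth knowing

Two numerical facts surface in the test suite and are properties of the
methods, not bugs:

* The exact two-sample KS test at group sizes 100/100 has true size 0.0364
  at the 0.05 level (the discrete null distribution of $D$ cannot attain
  0.05 exactly). Null-marker calibration is therefore measured over 5,000
  simulated cohorts so Monte Carlo error (SE ≈ 0.003) is small against
  that value; the ANOVA size is 0.05 essentially exactly.
* The asymptotic log-rank p-value and a 10,000-permutation label-shuffle
  p-value agree to about 0.01 at 30 subjects per group; the package reports
  the asymptotic value, matching standard survival-analysis practice.

Problem sizes used by the checks — 500 replicates for planted-effect
recovery at $n = 400$, $\beta = 1$; 5,000 replicates for null calibration;
22 cohorts × 400 samples for clustering recovery — were chosen once as
realistic desk-scale analogs of the full analysis.

## Reproducibility

Every source of randomness flows from an explicit integer seed: cohort
seeds are derived deterministically from the bundle seed, K-means uses its
own fixed seed argument, and `run_pipeline()` writes a manifest with an MD5
checksum of every output file plus a hash of the configuration. Two runs of
the same seeded configuration are byte-identical, including the manifest.

## Limitations

* Signature membership defaults are curated stand-ins; exact published
  lists should be supplied via GMT when fidelity matters.
* No covariate adjustment (age, stage, purity) anywhere; contrasts are
  marginal.
* No multiple-testing correction by default; the exported tables carry raw
  p-values.
* The quartile design discards the continuous score's information within
  groups; the per-marker Spearman correlation with the raw score is the
  complementary view.
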