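---
title: "Methods: spatially informed intra-tumor heterogeneity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially informed intra-tumor heterogeneity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetgeo)
```

This vignette documents the statistical model behind every `hetgeo`
estimator, the parameters and their defaults, the design of the synthetic
cohort generator, and the numerical and methodological decisions that were
left open by the problem statement and had to be settled one way or the
other. Code chunks are illustrative and not evaluated at build time.

## 1. Data model

A cohort consists of $P$ patients; patient $p$ contributes $m_p \ge 2$
tumor regions (optionally plus a normal sample). Each region has

- a TPM-scale expression profile over $G$ genes (all internal analysis is
  on $\log_2(\mathrm{TPM}+1)$, the standard variance-stabilizing choice
  for TPM-scale data; the transform is exposed as an argument wherever a
  matrix might already be on an analysis scale),
- a 2-D physical coordinate $(x, y)$ in centimeters, recorded on the cut
  surface of the resected tumor,
- optionally a somatic variant set, canonicalized as
  `chrom:pos:ref:alt` keys,

and each patient has overall-survival follow-up `(time, event)`.

## 2. Patient-level diversity

### Transcriptomic diversity Div(t)

Tumor-sample profiles are embedded with a single cohort-wide PCA
(`fit_pca()`): genes with TPM $\ge 1$ in at least 20 % of tumor samples
are kept, profiles are $\log_2(\mathrm{TPM}+1)$-transformed, and a
centered, unscaled `prcomp` is fitted. For patient $p$ with embedded
regions $x_1,\dots,x_{m_p}$ in the first $K = 15$ principal components,

$$\mathrm{Div}(t)_p = \frac{1}{m_p} \sum_{i=1}^{m_p} \lVert x_i - \bar{x} \rVert_2 .$$

Fifteen components is the default because in cohorts of this size
(hundreds of genes and up to low hundreds of samples in our simulations)
they retain the patient-level structure while discarding
gene-sampling noise; `n_pcs` is clipped to the available rank with a
warning.

### Physical diversity Div(p) and the normalized score

`physical_diversity()` applies the same mean-distance-to-centroid
statistic to the region coordinates. The normalized score is the plain
ratio $\mathrm{Div}(t)/\mathrm{Div}(p)$ (`normalized_diversity()`;
$\mathrm{Div}(p) = 0$ is an error, not an `Inf`). Tumors are classified
low/high ITH by the cohort median (`classify_ith()`; scores equal to the
median go to "low" so the high class is strictly above it).
`concordance_classify()` extends the median split to per-region scores
and calls a tumor *discordant* when its regions straddle the split.

### Genomic diversity and distance correlations

Genomic diversity is the median pairwise Jaccard distance
$1 - |A \cap B| / |A \cup B|$ over a tumor's variant sets. Association
between geometry and molecular divergence uses matched within-tumor
pairwise distances (pairs are never formed across tumors): physical
Euclidean distance vs either $1 - \rho_s$ (Spearman) transcriptomic
distance or Jaccard genomic distance, correlated by Spearman rank either
per tumor (with a $\rho > 0.30$ "strong trend" flag) or pooled.

## 3. Gene-level heterogeneity (IHS)

For each gene (row of any feature × sample matrix), three quantities:

**ITVS.** The random-intercept decomposition
$y_{ps} = \mu + b_p + \varepsilon_{ps}$,
$b_p \sim N(0, \sigma_B^2)$, $\varepsilon \sim N(0, \sigma_W^2)$, is
fitted by REML (`lme4::lmer`, singular fits tolerated) and
$\mathrm{ITVS} = \hat\sigma_W^2 / (\hat\sigma_W^2 + \hat\sigma_B^2)$. If
the fit fails, a balanced-ANOVA method-of-moments estimator is used
($B = \max(0, (\mathrm{MSB} - \mathrm{MSW})/n_0)$, $W = \mathrm{MSW}$).
REML was chosen over plain ANOVA moments because real cohorts are
unbalanced ($m_p$ varies 3–10); the two agree to $10^{-6}$ on balanced
designs (tested).

**PGOR and CCS.** All regions are clustered hierarchically (complete
linkage on Euclidean distance; complete linkage because co-clustering of
a patient's regions should mean *all* of them sit in one tight group, a
criterion single/average linkage dilute through chaining). For every cut
$k = 2, \dots, P$, $\mathrm{PGOR}(k)$ is the fraction of patients whose
regions share a single cluster. Patients with one sample are excluded
with a warning. The area under the curve is trapezoidal over the $P-1$
cut points, and $\mathrm{CCS} = 1 - \mathrm{AUC}/(P-1)$, so
$\mathrm{CCS}=0$ means every patient co-clusters at every cut. For
multi-feature PGOR (e.g. a signature sub-matrix), columns are z-scored
first so no single gene dominates the Euclidean metric.

**IHS.** $\mathrm{IHS} = \sqrt{\mathrm{ITVS}\cdot\mathrm{CCS}}$, binned
half-open at 0.25 / 0.50 / 0.75 (`[0, 0.25)` low, …, with 1.0 closed
into very-high). Genes with zero total variance get `NA` scores rather
than an arbitrary 0 or 1.

**Null reference and enrichment.** `nb_null_ihs()` draws i.i.d.
negative-binomial genes with no patient structure over the cohort shape;
such genes concentrate near IHS = 1, giving an interpretable ceiling.
`ihs_enrichment_rank()` tests whether a query gene set concentrates at
the low-IHS end of the ranking, using a weighted Kolmogorov–Smirnov
statistic with seeded gene permutations (`fgsea::fgseaSimple` over a
strictly decreasing centered rank statistic; ties in IHS are broken by
feature id to keep the ranking deterministic).

## 4. Subsampling: how many regions are enough

For a tumor with $m$ regions, `subsample_experiment()` re-estimates the
diversity scores on every $k$-subset of regions, for each $k$ in a
range. Subsets are enumerated exhaustively (`utils::combn`) whenever
$\binom{m}{k} \le 5000$, otherwise by seeded de-duplicated random draws.
Two crucial design choices:

- the PCA basis is fitted once on the full cohort and held fixed across
  subsets, so the comparison isolates sampling of regions rather than
  re-estimation of the embedding;
- spread is summarized by the population coefficient of variation
  $\mathrm{CV} = \mathrm{SD}/\mathrm{mean}$ and the coefficient of
  deviation $\mathrm{CD} = \sqrt{\tfrac1n\sum(\alpha_i-\alpha)^2}/\alpha$
  against the all-region gold standard $\alpha$; the two formulas
  coincide when $\alpha$ is the subset mean (tested). At $k=m$ there is
  one subset, so CV is `NA` and CD is exactly 0.

## 5. Prognostic signature pipeline

1. **Low-ITH filter**: genes with IHS strictly below 0.25 (the low-bin
   boundary). Strict, so a gene sitting exactly on the boundary is not
   "low".
2. **Univariate Cox screen** on per-cohort z-scored expression; a gene
   passes only if $p < 0.05$ with the *same* hazard direction in every
   training cohort. Genes constant in some cohort are flagged, not
   silently dropped.
3. **Bootstrap stability**: patients are resampled with replacement
   within each cohort `n_boot` times (default 2500) and the screen is
   repeated; genes passing in $\ge$ 80 % of replicates are kept.
4. **Combination search** with random survival forests
   (`ranger`, permutation importance, `num.threads = 1` and a derived
   seed per fit for bit-reproducibility): importance is averaged over
   replicate forests, genes are ranked, and each nested top-$j$ subset
   ($j = 2..25$) is scored by out-of-bag concordance
   ($1 -$ `prediction.error`); the best subset wins, ties going to the
   smaller one. A best concordance below 0.55 sets a `low_confidence`
   flag. Nested subsets rather than all $2^n$ combinations: the search
   space is the importance ranking, which keeps the procedure
   deterministic, interpretable and $O(n)$.
5. **Weights**: a multivariate Cox fit on the selected genes; the score
   of a sample is $\sum_g w_g \, z(\mathrm{expr}_g)$ with z-scoring
   performed *within the evaluation data* (so scoring needs no stored
   training means, at the cost of cohort-relative calibration — the
   usual trade-off for cross-platform signatures).

**Evaluation.** Prognosis: median-score split, Cox HR with CI, log-rank
test, and time-dependent cumulative/dynamic AUC with inverse probability
of censoring weights (Kaplan–Meier censoring distribution estimated by
`survival::survfit` on the flipped indicator; with no censoring the
estimator provably reduces to plain case/control concordance, and this
identity is tested). The default evaluation grid is 5 time points between
the 10th and 90th percentile of follow-up; mean AUC is reported.
ITH-robustness: median signature-gene IHS, proportion of discordant
tumors under the per-region score split, and the PGOR AUC of the
z-scored signature sub-matrix ($P-1$ is perfect).

## 6. Synthetic cohort generator

`simulate_cohort()` draws, per the config (`sim_config()` defaults in
parentheses, chosen to mimic a hepatectomy-style multi-region study and
freely adjustable):

- **Geometry**: per patient, $m_p$ uniform on 3–10 sampling points,
  uniform on a disc of radius 3 cm with rejection sampling enforcing a
  0.5 cm minimum spacing (bounded restarts; infeasible configurations
  error out rather than loop).
- **Expression** ($G = 500$ genes), built on the log2 scale as
  $v = \mu_g + b_{pg} + s + \varepsilon$ with gene baselines $\mu_g$
  (mean 4), patient effects $b_{pg} \sim N(0, \sigma_B^2)$
  ($\sigma_B = 1$), white noise, and a spatially correlated Gaussian
  field $s$ sampled via the Cholesky factor of the kernel matrix
  ($+10^{-8}I$ for numerical positive-definiteness). A fraction
  `spatial_fraction` (0.6) of the within-tumor variance
  ($\sigma_W = 0.5$, scalar or per-gene vector) is carried by the field,
  the rest by white noise. TPM is recovered as
  $\max(2^v - 1,\, 0)$. `sigma_within` accepts a per-gene vector, which
  is how benchmark cohorts with a known low-ITH gene class are made.
- **Kernel**: exponential $\exp(-d/\ell)$ by default ($\ell = 2$ cm), a
  rough, non-smooth field; a Gaussian kernel $\exp(-(d/\ell)^2)$ is
  selectable. This matters: under the exponential kernel the field
  variogram is linear at short range, so $\mathrm{Div}(t)$ grows like
  $\sqrt{\mathrm{Div}(p)}$ and the plain ratio over-corrects; under the
  Gaussian kernel with sampling spreads below $\ell$ the relation is
  close to linear and the ratio removes the geometric signal almost
  exactly. The property tests of the normalization therefore use the
  Gaussian kernel; the default stays exponential as the more
  conservative texture.
- **Mutations**: 100 truncal variants per patient plus 30 private
  variants per region, each private variant shared with another region
  with probability $\exp(-d/\mathrm{range})$ — so Jaccard distance
  increases with physical distance by construction.
- **Survival**: exponential proportional hazards, log-hazard
  $\sum_g \beta_g z_g$ over z-scored patient-mean log2 expression
  (defaults: $\beta = +0.5$ for g1–g5, $-0.5$ for g6–g10), baseline
  hazard 0.02, independent exponential censoring calibrated to a target
  censoring fraction (0.3). All-censored draws are retried on fresh
  sub-seeds a bounded number of times.
- **Reproducibility**: the master seed spawns named per-component
  sub-seeds, so e.g. regenerating survival does not perturb expression.

Known limits of the generator: tumors are 2-D discs (real cut surfaces
are irregular); the spatial field is stationary and isotropic; genes are
independent given the patient and field (no co-expression modules);
survival is exponential with proportional hazards; mutation sharing
ignores phylogeny beyond the trunk/private split.

## 7. Settled open questions, in one place

- $\log_2(\mathrm{TPM}+1)$ everywhere; transform exposed as an argument.
- PCA: centered, unscaled, cohort-wide, 15 components, tumor samples
  only, expression filter TPM $\ge 1$ in $\ge 20$ % of tumor samples.
- Clustering: complete linkage, Euclidean; z-scored columns for
  multi-feature matrices.
- ITVS: REML first, balanced-ANOVA moments fallback; `NA` for
  zero-variance genes.
- PGOR AUC: trapezoid over integer cuts; CCS normalized by $P-1$.
- IHS bins: half-open at 0.25/0.50/0.75, 1.0 included in very-high.
- Subsampling: fixed full-cohort basis; exhaustive up to 5000 subsets.
- Screen: $p<0.05$, direction consistent across all cohorts; bootstrap
  2500 × 80 %; forest: 10 replicates × 500 trees, nested top-$j$,
  OOB-concordance selection.
- Scoring: Cox-weighted sum of z-scores, z within evaluation data.
- td-AUC: IPCW cumulative/dynamic, KM censoring weights, mean over a
  5-point 10–90 % follow-up grid.

Problem sizes in the tests and analysis scripts (cohort sizes, gene
counts, boot/replicate counts) are our own choices, scaled so the whole
suite runs in minutes on one core.

## 8. Caveats

Estimator variance at small $m_p$ is substantial: with fewer than ~5
regions per tumor, CCS takes few distinct values and IHS rankings are
noisy (the subsampling module exists precisely to quantify this; in our
simulations the largest stability gain is from 2 to 3 regions). The
low-ITH filter at IHS < 0.25 is conventional, not optimized. The
normalized diversity ratio removes the geometric confounder only to the
extent that the molecular–physical relation is linear through the
origin; strongly non-linear spatial correlation structures (see the
kernel discussion above) are only partially corrected.
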