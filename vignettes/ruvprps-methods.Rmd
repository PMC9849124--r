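---
title: "Removing unwanted variation from bulk RNA-seq with RUV-III and pseudo-replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing unwanted variation from bulk RNA-seq with RUV-III and pseudo-replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruvprps)
```

## The problem

Gene-level counts from large bulk RNA-seq compendia carry several kinds of
variation nobody ordered: sequencing depth (library size) that differs
between samples and drifts between processing periods, batch effects from
plates, flow-cell chemistries and facilities, and — in tumor collections —
the varying fraction of cancer cells in each biopsy (tumor purity). Global
scale-factor normalizations assume every gene's count is proportional to
library size, which is false: some genes respond super-proportionally, some
not at all, some inversely, so dividing by a single per-sample factor fixes
some genes while *introducing* library-size variation into others.
Regression-style batch correction assumes biology is balanced across batches
and removes whatever aligns with the batch labels, biology included. And no
per-sample scale factor can touch purity at all, because purity is a
property of the tissue, not the assay.

`ruvprps` implements a factor-analytic alternative: RUV-III, driven by
pseudo-replicates of pseudo-samples (PRPS), with the control-gene selection
recipes, the diagnostic toolkit and a synthetic-data generator that realizes
this unwanted-variation taxonomy so everything can be tested without any
external download.

## The model and the estimator

Let $Y$ be the $m \times n$ matrix of $\log_2(\text{count} + 1)$ values for
$m$ assays and $n$ genes. The working model is

$$Y = \mathbf{1}\mu + M X \beta + W \alpha + \varepsilon,$$

where $M$ is the binary $m \times m_1$ mapping matrix assigning each assay
to one of $m_1$ distinct (pseudo-)samples, $X\beta$ is the biology of
interest indexed by sample, $W$ ($m \times k$) holds $k$ unobserved unwanted
factors with loadings $\alpha$, and $W \perp \mathbf{1}$. Negative control
genes are a column subset assumed to satisfy $\beta_c = 0$.

Averaging within replicate sets is the projection
$P_M = M(M^\top M)^{-1}M^\top$; its complement $R_M = I - P_M$ annihilates
$\mathbf{1}\mu$ and $MX\beta$ (both constant within replicate sets), so the
replicate residual $R_M Y$ carries unwanted variation and noise only. The
fit proceeds in three steps:

1. take the first $k$ left singular vectors $U^{(k)}$ of $R_M Y$ and set
   $\hat\alpha^{(k)} = U^{(k)\top} Y$;
2. estimate $W$ by regressing the column-centered controls
   $(I - P_1)Y_c$ on $\hat\alpha^{(k)}_c$,
   $\hat W^{(k)} = (I - P_1) Y_c\, a_c^\top (a_c a_c^\top)^{-}$ with
   $a_c = U^{(k)\top} Y_c$;
3. form $Y^{(k)} = Y - \hat W^{(k)} \hat\alpha^{(k)}$.

Gene means are never subtracted — only the estimated unwanted component is
removed, which is why untargeted variation (e.g. purity, when no purity
PRPS are supplied) survives the adjustment. In the noiseless model with
controls truly null and $\mathrm{span}(W)$ recoverable from the replicate
residuals, the adjustment is exact; `test-acceptance.R` verifies recovery to
$10^{-8}$ and the equivalence of the SVD route with the
eigendecomposition of $R_M Y Y^\top R_M$.

Numerical choices: the SVD of $R_M Y$ is the production path
(eigendecomposition of the $m \times m$ Gram matrix is retained as a test
oracle); the bracketed inverse in step 2 is a Moore–Penrose pseudo-inverse
with a relative singular-value cutoff of $10^{-12}$, because $a_c$ is easily
rank-deficient for small control sets; $k = 0$ is allowed as an identity fit
so sweeps and ablations are uniform; a fit with $R_M Y = 0$ (no replicate
contrast) is an error, not a silent zero.

## PRPS: manufacturing replicates

TCGA-scale studies have no technical replicates, and replicates could not
expose purity anyway (a sample's purity is the same in every replicate).
PRPS sidesteps both problems. Assays that are roughly homogeneous in biology
*and* in an unwanted factor are averaged into a pseudo-sample;
pseudo-samples sharing biology form a pseudo-replicate set, so their
differences — which are almost entirely unwanted variation — feed $R_M Y$.

Two recipes are implemented:

* **Categorical batches** (`make_batch_prps`): for each biology group with
  at least `min_per_batch` assays in at least `min_batches` batches, average
  each qualifying (biology, batch) cell. Defaults are 3 and 2; sparse
  designs benefit from `min_per_batch = 2`, which is what the benchmark
  pipeline uses on the time-structured fixture.
* **Continuous factors** (`make_continuous_prps`): within each stratum,
  average the `n_extreme` highest and the `n_extreme` lowest assays by the
  factor (library size, purity) into a high/low pair. Ties are broken by a
  stable sort on assay id. Pairs from all strata of one biology group share
  one replicate set.

Averaging is done on the $\log_2$ scale, since that is the scale the
estimator consumes; set labels are namespaced per recipe so sets from
different recipes never merge accidentally; real assays default to singleton
samples.

One recipe decision was genuinely open: purity pairs per subtype (4 pairs on
the purity fixture) leave the estimated purity loadings noisy enough that
attenuation keeps a purity-correlated residual direction in the data
(roughly half the purity $R^2$ survived). Forming the pairs within
subtype-by-plate cells — assays even more homogeneous in unwanted variation,
which is the PRPS principle — yields 48 pseudo-samples and removes ~90% of
the purity $R^2$. `benchmark_purity_removal()` and `ruv_normalize()`
therefore stratify purity pairs by plate (`purity_within`), and we recommend
that whenever plates are large enough.

## Choosing controls and k

`select_ncg()` intersects per-gene criteria (`gene_criterion`): one-way
ANOVA F against a biological factor (keep low), Spearman correlation with a
covariate such as purity, library size or a housekeeping average (keep
low/high, absolute or signed), each with a threshold or a rank count, and
each optionally evaluated on its own matrix (biology-F on normalized data,
library-size correlation on raw counts). Selection is monotone in the
thresholds and deterministic, with rank ties broken by gene id.

There is no closed-form chooser for $k$. The honest tool is `sweep_k()`:
refit for a range of $k$ and watch the diagnostics; the control-gene
replicate residual norm is provably non-increasing in $k$, while
biology-separation metrics flag over-removal. For the simulated fixtures the
structural dimension is known by construction — one library-size direction,
$(\text{plates} - 1)$ plate contrasts, one purity direction when purity is
on — and is recorded in the generator's truth object; the benchmarks fit at
exactly that dimension.

## The diagnostic toolkit

All of the global and gene-level diagnostics used to find and score
unwanted variation are in the `assess` layer: RLE medians/IQRs
(`rle_stats`), PCA on gene-centered values with a deterministic sign
convention (`pca_scores`), cumulative-PC regression $R^2$
(`r2_cumulative_pcs`), the Rozeboom squared vector correlation
$1 - \prod(1 - \rho_i^2)$ over canonical correlations — which provably
reduces to the regression $R^2$ for a single quantitative variable
(`vector_correlation`), silhouette and k-means/ARI on the first three PCs
(`silhouette_mean`, `ari_by_label`; the clustering is k-means with 25
restarts and a required seed, since the reference protocol leaves the
clusterer unspecified), per-gene rank-sum DE p-values with the fraction
below 0.05 (`de_pvalues`), partial correlation (`partial_correlation`), and
rank-based signature scoring with analytic min–max normalization
(`signature_score`, `purity_score`).

Two conventions deserve a note. The two-group DE comparison between low and
high library-size (or purity) samples is an *unpaired* design, so the
default test is the two-sample rank-sum test; the paired signed-rank variant
is available via `paired = TRUE` for genuinely matched designs. And the
signature score normalizes the mean rank of a set of size $s$ by its
analytic extremes $(s+1)/2$ and $n-(s-1)/2$, so scores span $[0, 1]$ exactly
and are invariant under monotone transforms of an assay; the degenerate
"set = all genes" case is defined as 0.5.

## What the simulator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts
($\mathrm{var} = \mu + \phi\mu^2$, default $\phi = 0.1$) around a per-cell
$\log_2$ mean composed of: a baseline $\mu_g \sim N(8, 2^2)$ clipped to
$[0, 14]$ (post-filter bulk genes typically sit at hundreds of counts;
at much lower baselines the $+1$ pseudocount makes the additive log-scale
structure visibly nonlinear); subtype effects $\beta \sim N(0, 1)$ for a
non-null half of genes; a gene-specific library-size response
$\gamma_g(\ell_i - \bar\ell)$ with class coefficients $\gamma \in \{1, 1.5,
0, -0.5\}$ mixed 50/20/20/10 — the proportional, super-proportional,
independent and inverse response classes; additive per-gene plate effects
$\delta \sim N(0, 0.5^2)$, optionally with a chemistry offset shared by
plates of one chemistry; and, when purity is enabled, a tumor/stroma
mixture on the *count* scale,
$\log_2\!\big(p_i 2^{\mu_g} + (1 - p_i) 2^{s_g}\big)$, because bulk tissue
mixes cell populations linearly in molecules, not in logs. Affected genes
get a stromal profile displaced by a fixed $\pm 3$ $\log_2$ units (random
sign): compartment-specific genes differ by large folds, and a
fixed-magnitude displacement keeps "affected" meaning affected. Purity is
$\mathrm{Beta}(5, 2)$, library size log-normal with a per-time-stratum
shift, and plates are nested in time strata with assays dealt round-robin
within subtype (`plate_scheme = "balanced"`); a `"random"` scheme is
available to study composition imbalance, under which no normalization can
reach a plate vector correlation near zero because plates then genuinely
differ in biology.

Three deterministic fixtures package these conditions: `tiny`
(12 × 60, fast unit checks), `readlike` (200 × 2,000, two time strata
with a 4-fold library-size shift, six plates nested in time, four
subtypes), and `brcalike` (300 × 2,000, purity mixture plus two
chemistries nested in six plates). The generator records every model symbol
(design, $\beta$, $\mu$, $\gamma$, plate effects, stromal profiles,
generative library sizes, purity, the full $\log_2$ mean) so tests can
assert against truth rather than against the implementation.

What the simulator does **not** emulate: gene length and GC content
(within-sample effects, out of scope), read-level error, count-scale
zero-inflation beyond the negative binomial, correlated gene modules, or
annotation artifacts (users supply exclusion lists). Passing the recovery
benchmarks therefore demonstrates that the estimator removes the *kinds* of
structure the model describes at realistic magnitudes — not that any real
dataset is fully described by that model.

## Problem sizes and calibration of the checks

The test suite and the acceptance script run, by design, at desk scale:
exactness on an 8 × 30 noiseless instance ($10^{-8}$), path equivalence on
twenty 8 × 20 instances, recovery on the 200 × 2,000 and 300 × 2,000
fixtures, null calibration of the DE diagnostic on 2,000 genes with 50 + 50
random groups (fraction of $p < 0.05$ within $0.05 \pm 0.02$ and
Kolmogorov–Smirnov uniformity), and the poorly-chosen-PRPS experiment with
20% of biology labels shuffled, ten repeats averaged. On the fixtures,
RUV-III at the structural dimension removes ≥ 80% of the mean absolute
gene–library-size correlation, brings the plate vector correlation below
0.2 (its permutation-null level is ≈ 0.12–0.18 at these sizes, so "below
0.2" means "at the null"), recovers subtypes at least as well as raw data,
removes ≥ 80% of the purity $R^2$ when purity PRPS are included, and
*retains* purity when they are not — the adjusted purity $R^2$ typically
rises, since removing the masking chemistry and library-size variation
unmasks it; we assert retention one-sidedly (not reduced by more than 20%)
for exactly that reason.

## Known limitations

* Attenuation: with few, small pseudo-replicate sets the estimated loadings
  are noisy and removal is partial (errors-in-variables); the remedy is more
  or larger pseudo-samples, not a larger $k$.
* The $+1$ pseudocount bends the additive log-scale model for genes whose
  counts sit near zero in any stratum; the group-aware low-expression filter
  (at least 15 counts in at least 20% of the smallest biology-by-time cell)
  exists to keep such genes out.
* Biology-batch confounding: when batches genuinely differ in biological
  composition, batch-association metrics have a floor no normalization can
  cross, and aggressive removal would eat biology; PRPS mitigates but cannot
  abolish this.
* $k$ remains a judgment call on real data; `sweep_k()` plus prior biology
  is the supported workflow, and over-large $k$ can remove signal.
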