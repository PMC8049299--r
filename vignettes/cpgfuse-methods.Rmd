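---
title: "Modeling histone-mark abundance from binned TF signal, stratified by promoter CpG content"
author: "cpgfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling histone-mark abundance from binned TF signal, stratified by promoter CpG content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgfuse)
```

## The model

`cpgfuse` asks which transcription factors (TFs) are associated with the
abundance of a histone modification (HM) at promoters, and whether those
associations depend on promoter CpG content. The response for one HM at one
gene is its mean ChIP-seq signal in a window from 500 bp upstream to 500 bp
downstream of the TSS. The features are the per-bin mean signals of $m$ TFs in
$k$ equal bins of that window (default $k = 10$, 100-bp bins), indexed
upstream-to-downstream in *gene* orientation, so bin 1 means the same promoter
position for every gene; minus-strand windows are bin-reversed. All signals are
log-transformed (natural log, pseudocount 1) and scaled per feature to
$[0, 1]$, which tames right-skewed raw counts and differences in antibody
affinity or sequencing depth.

The fitted model is a generalized fused LASSO:

$$
\hat\beta = \arg\min_\beta \;
\|y - \beta_0 - X\beta\|_2^2
+ \lambda_1 \|\beta\|_1
+ \lambda_2 \sum_{(i,j) \in E} |\beta_i - \beta_j|,
$$

where $E$ joins adjacent bins within each TF (a chain per TF, no edges across
TFs). The $\ell_1$ term selects few TFs; the fusion term makes per-bin
coefficients of one TF locally constant, matching the smoothness of real
binding profiles and making the per-bin coefficient heat maps interpretable.
The quadratic term is an unscaled sum of squares — every closed-form special
case in the documentation and tests uses this convention (e.g. on an
orthonormal centered design with $\lambda_2 = 0$ the solution soft-thresholds
$X^\top y$ at $\lambda_1 / 2$).

## Optimization and numerical choices

The solver is accelerated proximal gradient descent (FISTA with a
function-value restart) on the Gram form of the centered problem; the step is
$1 / (2\,\lambda_{max}(X^\top X))$. The proximal operator of the combined
penalty decomposes exactly on chains: total-variation denoising per chain
(Condat's direct algorithm) followed by elementwise soft-thresholding at
$\lambda_1 t$. Convergence is declared when the relative objective decrease
falls below `tol` (default `1e-9`); hitting `max_iter` flags the fit instead
of failing silently. A final refinement step reads off the fused block and
sign pattern, solves the implied stationarity system exactly, and keeps the
refined solution only if it preserves the pattern and lowers the objective;
this routinely brings the solution to near machine precision, which the test
suite exploits for oracle and KKT checks.

Fused *blocks* — maximal runs of numerically equal coefficients within a
chain — are detected at a relative tolerance of `1e-6 * max(abs(beta))`
(proximal solutions are equal only up to solver tolerance, unlike path
solutions). The model degrees of freedom are the number of nonzero blocks,
reducing to the usual LASSO count for $k = 1$. Constant feature columns
normalize to all zeros: they carry no information, and this keeps the
$[0, 1]$ contract.

## Penalty selection

Performance is assessed by 5-fold nested cross-validation: inner folds
(default 3 — a count the method leaves open; 3 keeps the inner training sets
reasonably sized) select $(\gamma, \lambda_2)$ by mean held-out RSS, where
$\gamma = \lambda_1 / \lambda_2$ runs over $\{0\} \cup \{10^i\,|\,i=-5..5\}$
($\gamma = 0$ is fusion-only). Because the solver evaluates the objective at
grid points rather than tracing the full solution path, the $\lambda_2$ grid
is geometric: 30 values from the smallest $\lambda_2$ that fuses every chain
to a single block (found by a doubling search at $\gamma = 0$) down five
orders of magnitude. Ties in inner-fold RSS resolve towards the more
regularized model (larger $\lambda_2$, then larger $\gamma$). Fold assignment
is a deterministic function of the run seed. The final model refits all genes
of the class at penalties selected by a fresh inner-fold search on the full
class.

## CpG partition

CpG content — the count of CG dinucleotides in the promoter window — is
bimodal across promoters. The package fits a two-component Gaussian mixture
to the raw per-gene counts by EM with k-means initialization plus nine
randomized restarts under a fixed seed (fitting the raw totals avoids the
arbitrary histogram bin width), and splits the genes where the two weighted
component densities intersect between the means:
$w_1 N(x;\mu_1,\sigma_1^2) = w_2 N(x;\mu_2,\sigma_2^2)$. A vanishing
component or a missing root is an error, not a silent fallback. Genes below
the threshold are CpG-poor, the rest CpG-rich; separate models are trained
per class (plus an all-genes model to control for training-set size), with
normalization recomputed within each class — per-class feature spaces match
the per-class models (the scope of normalization is left open by the method;
per-class is consistent with training separate models per set). Whether the
response is also log-unit normalized is likewise open; the default
(`normalize_response = TRUE`) treats it like the features, and the flag
restores raw window means.

## Association inference

A TF's contribution to a fitted model is scored by an approximate-refit
F-test: the reduced model zeroes the TF's $k$ coefficients without
retraining (refitting per TF would be intractable at hundreds of TFs), giving

$$
F = \frac{(RSS_0 - RSS_{full}) / (df_{full} - df_0)}
         {RSS_{full} / (N - df_{full} - 1)},
$$

with block degrees of freedom throughout. The numerator difference is taken
as $df_{full} - df_0$, the conventional positive nested-model order (zeroing
a TF removes blocks, so this is nonnegative; the $F$ distribution requires
positive df). Zeroing coefficients of an optimized fit cannot reduce the
penalized objective's quadratic part below the optimum's, so
$RSS_0 \ge RSS_{full}$ holds exactly — a property the suite asserts. Per
model, the TFs with the ten lowest p-values below $\alpha = 0.005$ are
reported with the sign of their summed bin coefficients; no multiple-testing
correction is applied across TFs, matching the fixed-$\alpha$ plus top-10
reporting scheme. The zero-out $RSS_0$ and penalized df make the test's null
calibration approximate; the test suite therefore asserts ranking properties
(planted TFs rank above null TFs; signs are recovered) rather than exact
type-I control.

## Partial correlations between marks

For each unordered pair of HMs, the partial correlation given all remaining
HMs is the Pearson correlation of the two OLS residual vectors (intercept
included — the standard definition). Significance comes from a permutation
test: one residual vector is permuted $n = 10000$ times, the other held
fixed. Two numerical choices deviate deliberately from a literal reading of
the procedure and are reversible by flags: the test is two-sided on $|\rho|$
(strongly negative correlations are marked significant in the reference
results, which a one-sided "larger than observed" rule could not produce),
and the p-value uses the add-one correction $(1 + \#\{|\rho_\sigma| \ge
|\rho_{obs}|\}) / (n + 1)$, a valid permutation p that is never exactly
zero. Pairs are Bonferroni-corrected within each CpG class and thresholded
at $\alpha = 0.01$.

## Class performance comparison

Per HM, the five outer-fold Pearson correlations of the rich and poor models
are compared by a two-sample Wilcoxon rank-sum test with exact small-sample
p-values (the fold test sets contain different genes in the two classes, so
pairing is undefined; a paired variant is available). When ties occur only
within a group the exact Mann-Whitney distribution still applies and is used
directly. P-values are Benjamini-Hochberg corrected across the HMs of a run
and thresholded at $\alpha = 0.05$.

## The synthetic generator

Real promoter ChIP-seq matrices require consortium-scale downloads, so the
package ships a generator that emulates the statistical structure the
analysis assumes, with full ground truth:

* **CpG counts**: a two-Gaussian mixture, rounded and truncated at zero.
  Defaults — weights $(0.27, 0.73)$, matching the reported fraction of
  CpG-poor promoters; means $(20, 60)$ and sds $(5, 8)$, a clear bimodal
  separation at realistic CpG-count scales. Only bimodality and the
  intersection threshold matter downstream, so no discrete count model is
  used.
* **TF signals**: exponentials of Gaussians (log-normal), the minimal
  emulation of right-skewed positive accumulated read counts implied by
  log-normalizing; default log-location 2, log-scale 1. This is an
  assumption of the generator, not an inference about real data.
* **HM responses**: sparse class-dependent linear combinations of the
  *normalized* TF bins (the model's feature space, so recovery compares like
  with like), plus Gaussian noise, shifted to be nonnegative.
  `noise_sd_for_r2()` calibrates the noise to a target explained-variance
  fraction. The default planted structure includes a TF whose sign flips
  between classes (which also flips the sign of an HM-HM coupling) and a TF
  exclusive to the poor class.

A single seed governs everything through fixed sub-streams (counts: `seed`;
TF matrix: `seed + 1`; noise: `seed + 2`), so components regenerate
bit-exactly in isolation. Signal matrices are serialized at 17 significant
digits so a TSV round trip reproduces the doubles exactly; derived report
tables use 12 digits. What the generator does *not* emulate: read-level
noise, peak shapes, replicate structure, TF-TF dependence beyond the planted
linear structure, or spatial autocorrelation of coverage. Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the model's own assumptions, not robustness to everything real ChIP-seq
exhibits.

## Problem sizes used in the checks

The recovery study runs at 2000 genes, 50 TFs, 10 bins, 5 planted TFs per
class and noise targeting $R^2 \approx 0.8$ over 20 seeds; penalty selection
in simulation studies uses a reduced grid ($\gamma \in \{0, 0.1, 1\}$ or
$\{0, 0.1, 1, 10\}$ with 8-10 $\lambda_2$ values, 3 folds), which the
package adopts as its simulation default — the full $12 \times 30$ grid
changes selected penalties little on planted-linear data while multiplying
cost. Recovery and the noiseless ceiling are evaluated on the raw (linear)
response scale, where the planted construction is exact; the pipeline's
default log-unit response normalization is a monotone transform that
preserves ranking-level conclusions. The acceptance script runs the full
pipeline at 1200 genes, 15 TFs and 3 HMs.

## Known limitations

* The zero-out F-test is conservative or anti-conservative in ways that
  depend on feature correlation; only its ranking behaviour is validated.
* The EM split can legitimately fail on unimodal count distributions — by
  design it errors rather than forcing a threshold.
* `gamma = Inf` (pure LASSO limit) is not on the default grid, matching the
  reference grid.
* The extract mode reads any coverage format rtracklayer imports (bigWig,
  bedGraph, wig); bigWig inputs are exercised by users, not by the text-only
  test fixtures.
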