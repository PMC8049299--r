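# cpgfuse

Which transcription factors (TFs) track the abundance of a histone
modification (HM) at promoters — and do the associations depend on promoter
CpG content? `cpgfuse` answers this with a CpG-stratified, spatially
resolved regression analysis of promoter ChIP-seq signal, built for
epigenomics analysts who have (or simulate) per-promoter TF and HM signal
matrices.

## The method

For each gene, the HM response is the mean ChIP-seq signal in a ±500 bp
window around the TSS; the features are per-bin means of each TF's signal in
ten 100-bp bins of that window (strand-aware, bin 1 most upstream in gene
orientation). Signals are log-transformed and scaled to [0, 1] per feature.
Per HM and per CpG class, the model is a generalized fused LASSO:

```
argmin_b  || y − b0 − X b ||²  +  λ1 ||b||₁  +  λ2 Σ_(i,j)∈E |b_i − b_j|
```

where E chains adjacent bins within each TF. Penalties are chosen by 5-fold
nested cross-validation (inner folds minimize held-out RSS over a
γ = λ1/λ2 and λ2 grid). Downstream:

* **CpG partition** — per-promoter CpG counts are fitted with a
  two-Gaussian mixture (EM); the intersection of the weighted densities
  splits promoters into CpG-poor and CpG-rich classes, modeled separately.
* **Association ranking** — each TF is scored by an approximate-refit
  F-test (its coefficients zeroed, no retraining) with fused-block degrees
  of freedom; per model the ten smallest p-values below α = 0.005 are
  reported with signs.
* **Partial correlations** — for each pair of HMs given all others, the
  Pearson correlation of OLS residuals, with a 10 000-permutation test and
  Bonferroni control at α = 0.01, per CpG class.
* **Class comparison** — outer-fold Pearson correlations of the rich vs
  poor models are compared per HM by an exact Wilcoxon rank-sum test with
  Benjamini-Hochberg correction (α = 0.05).

A synthetic-data module generates data with this exact structure — bimodal
CpG counts, log-normal TF signals, sparse class-dependent linear HM
responses — with planted ground truth, so the whole pipeline is testable
end to end.

## Worked example

```r
library(cpgfuse)

cfg <- synthetic_config(n_genes = 300, n_tfs = 6, seed = 5,
                        planted = list(HM1 = list(
                          rich = list(`1` = rep(1, 10)),
                          poor = list(`1` = rep(-1, 10), `3` = rep(1, 10)))),
                        noise_sd = 0.1)
ds <- generate_dataset(cfg)
part <- fit_bimodal_split(ds$cpg_counts, seed = 2)
part
#> CpG-content promoter partition (two-Gaussian fit)
#>   components: N(20.68, 5.17^2) w=0.278 | N(60.06, 7.92^2) w=0.722
#>   threshold = 35.673: 83 CpG-poor, 217 CpG-rich promoters

idx <- which(part$labels == "poor")
Xn  <- normalize_log_unit(ds$tf_raw[idx, , drop = FALSE])
yn  <- normalize_log_unit(ds$hm_raw[idx, , drop = FALSE])[, 1]
cv  <- cv_fused_lasso(Xn, yn, n_bins = 10, gamma_grid = c(0, 0.1, 1, 10),
                      n_lambda2 = 8, seed = 9)
cv
#> Nested cross-validated chain fused LASSO (5 outer / 3 inner folds)
#>   mean outer-fold Pearson = 0.923 (range 0.749..0.989)
#>   final penalties: gamma = 0.1, lambda2 = 0.7565

rank_associations(tf_association(cv$final_fit, Xn, yn))
#>   tf_name   coef_sum     sign       rss0     f_stat df_num df_den      p_value
#> 1     TF1 -1.3354480 negative 25.6878826 8042.01847      1     78 1.885862e-80
#> 2     TF3  1.1311047 positive 19.8746472 6204.43693      1     78 4.186370e-76
#> 3     TF4 -0.1241567 negative  0.4920118   77.52643      1     78 2.580476e-13
#>   untested rank
#> 1    FALSE    1
#> 2    FALSE    2
#> 3    FALSE    3
```

The two TFs planted in the CpG-poor class are recovered as the top two
associations with the planted signs (TF1 negative, TF3 positive); the
threshold lands near the true mixture intersection (34.86). `run_pipeline()`
wraps all stages (ingest/synthesize, split, per-class models, associations,
partial correlations, class comparison) into one reproducible, config-driven
run whose TSV/JSON artifacts are byte-identical across reruns of the same
config.

Real-data inputs enter either as TSV matrices (`read_matrix_tsv()` dialect)
or through the extract mode: a GTF/BED annotation (`promoter_windows()`), a
genome FASTA for CpG counting (`count_cpg()`), and per-track coverage
readable by rtracklayer (bigWig/bedGraph/wig) via
`extract_signal_matrix()`.

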