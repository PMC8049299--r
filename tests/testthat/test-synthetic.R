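test_that("config validation rejects malformed inputs", {
  expect_error(synthetic_config(cpg_mixture = list(weight = c(0.6, 0.6),
                                                   mean = c(1, 2),
                                                   sd = c(1, 1))),
               "summing to 1")
  expect_error(synthetic_config(cpg_mixture = list(weight = c(0.5, 0.5),
                                                   mean = c(1, 2),
                                                   sd = c(-1, 1))),
               "nonnegative")
  expect_error(synthetic_config(noise_sd = -0.1), "nonnegative")
  expect_error(synthetic_config(n_tfs = 6,
                                planted = list(HM1 = list(
                                  rich = list(`9` = rep(1, 10))))),
               "planted TF indices")
  expect_error(synthetic_config(planted = list(HM1 = list(
    rich = list(`1` = rep(1, 3))))), "length n_bins")
})

test_that("CpG counts follow the mixture: moments, labels, degeneracy", {
  # degenerate point-mass mixture: all counts 0, both components drawn
  cfg0 <- synthetic_config(n_genes = 500, n_tfs = 5,
                           cpg_mixture = list(weight = c(0.5, 0.5),
                                              mean = c(0, 0), sd = c(0, 0)),
                           planted = NULL, seed = 3)
  cp0 <- generate_cpg_counts(cfg0)
  expect_true(all(cp0$counts == 0))
  expect_true(all(table(cp0$component) > 150)) # roughly per weights

  # analytic mixture moments at n = 1e4, within 3 standard errors
  cfg <- synthetic_config(n_genes = 10000, n_tfs = 5,
                          cpg_mixture = list(weight = c(0.5, 0.5),
                                             mean = c(20, 60), sd = c(3, 3)),
                          planted = NULL, seed = 11)
  cp <- generate_cpg_counts(cfg)
  mu <- 0.5 * 20 + 0.5 * 60
  v <- 0.5 * (9 + (20 - mu)^2) + 0.5 * (9 + (60 - mu)^2)
  expect_lt(abs(mean(cp$counts) - mu), 3 * sqrt(v / 10000))
  # variance within 3 SEs, using the analytic fourth central moment
  d <- c(20, 60) - mu
  mu4 <- sum(0.5 * (3 * 81 + 6 * 9 * d^2 + d^4))
  se_var <- sqrt((mu4 - v^2) / 10000)
  expect_lt(abs(var(cp$counts) - v), 3 * se_var)
  expect_identical(levels(cp$label), c("poor", "rich"))
})

test_that("generation is seed-deterministic with documented sub-streams", {
  cfg <- small_synth(seed = 21)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$tf_raw, d2$tf_raw)
  expect_identical(d1$hm_raw, d2$hm_raw)
  expect_identical(d1$cpg_counts, d2$cpg_counts)
  # standalone regeneration of a sub-stream matches the composed dataset
  expect_identical(generate_tf_signals(cfg), d1$tf_raw)
  d3 <- generate_dataset(small_synth(seed = 22))
  expect_false(identical(d1$tf_raw, d3$tf_raw))
})

test_that("TF signals are log-normal with TF-major column order", {
  cfg <- synthetic_config(n_genes = 40, n_tfs = 2, n_bins = 3,
                          planted = NULL, seed = 2,
                          background = list(location = 1.5, scale = 0.8))
  tf <- generate_tf_signals(cfg)
  expect_gt(min(tf), 0)
  expect_identical(colnames(tf),
                   c("TF1:1", "TF1:2", "TF1:3", "TF2:1", "TF2:2", "TF2:3"))
  # zero scale collapses every entry to exp(location)
  cfg0 <- synthetic_config(n_genes = 10, n_tfs = 2, n_bins = 3,
                           planted = NULL, seed = 2,
                           background = list(location = 1.5, scale = 0))
  expect_equal(unname(generate_tf_signals(cfg0)[1, 1]), exp(1.5))
  expect_equal(var(as.numeric(generate_tf_signals(cfg0))), 0)
})

test_that("responses invert the linear model: null, correlation, OLS recovery", {
  # empty planted mapping, no noise: constant response
  cfgn <- synthetic_config(n_genes = 50, n_tfs = 4, planted = NULL,
                           noise_sd = 0, seed = 5)
  dsn <- generate_dataset(cfgn)
  expect_equal(var(dsn$hm_raw[, 1]), 0)

  # one TF, unit coefficient on every bin, no noise: response is a perfect
  # linear image of that TF's mean normalized bin signal within each class
  cfg1 <- synthetic_config(n_genes = 120, n_tfs = 4,
                           planted = list(HM1 = list(rich = list(`2` = rep(1, 10)),
                                                     poor = list(`2` = rep(1, 10)))),
                           noise_sd = 0, seed = 6)
  ds1 <- generate_dataset(cfg1)
  for (cl in c("poor", "rich")) {
    idx <- which(ds1$truth$label == cl)
    Xn <- normalize_log_unit(ds1$tf_raw[idx, , drop = FALSE])
    mean_bins <- rowMeans(Xn[, 11:20])
    expect_lt(abs(cor(ds1$hm_raw[idx, 1], mean_bins) - 1), 1e-9)
  }

  # least-squares identifiability: OLS on the true support recovers the
  # planted coefficients at zero noise
  cfg2 <- small_synth(seed = 7, noise_sd = 0)
  ds2 <- generate_dataset(cfg2)
  planted <- cfg2$planted$HM1
  for (cl in c("poor", "rich")) {
    idx <- which(ds2$truth$label == cl)
    Xn <- normalize_log_unit(ds2$tf_raw[idx, , drop = FALSE])
    cols <- unlist(lapply(as.integer(names(planted[[cl]])),
                          function(t) ((t - 1) * 10 + 1):(t * 10)))
    fit <- lm.fit(cbind(1, Xn[, cols]), ds2$hm_raw[idx, 1])
    truth <- unlist(planted[[cl]])
    expect_lt(max(abs(fit$coefficients[-1] - truth)), 1e-6)
    expect_lt(sum(fit$residuals^2), 1e-12)
  }

  # planted index beyond m rejected at generation time too
  bad <- small_synth(seed = 1)
  bad$planted$HM1$rich <- list(`40` = rep(1, 10))
  cp <- generate_cpg_counts(bad)
  tf <- generate_tf_signals(bad)
  bad$n_hms <- 1L
  expect_error(generate_hm_response(tf, cp$label, bad), "exceeds")
})

test_that("dataset dimensions, TSV round trip, and noise calibration", {
  cfg <- small_synth(seed = 9, n_genes = 60)
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$tf_raw), c(60L, 60L))
  expect_identical(dim(ds$hm_raw), c(60L, 1L))
  expect_identical(length(ds$cpg_counts), 60L)

  tmp <- tempfile(fileext = ".tsv")
  write_matrix_tsv(ds$tf_raw, tmp)
  back <- read_matrix_tsv(tmp)
  expect_identical(unname(back), unname(ds$tf_raw))
  expect_identical(rownames(back), rownames(ds$tf_raw))

  # noise_sd_for_r2 hits the targeted explained-variance fraction
  cfg2 <- small_synth(seed = 12, n_genes = 2000)
  ns <- noise_sd_for_r2(cfg2, r2 = 0.8)
  cfg2$noise_sd <- ns
  ds2 <- generate_dataset(cfg2)
  r2 <- var(ds2$truth$noiseless[, 1]) /
    (var(ds2$truth$noiseless[, 1]) + ns[1]^2)
  expect_lt(abs(r2 - 0.8), 0.02)
})
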