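test_that("F statistic reproduces hand arithmetic and the OLS refit oracle", {
  # worked arithmetic: RSS0=120, RSSfull=100, df 3 vs 5, N=106
  expect_equal(cpgfuse:::.f_stat(120, 100, 5 - 3, 106 - 5 - 1), 10)

  # pure OLS (k = 1, no penalties) on an orthogonal design: the zero-out F
  # equals the textbook nested-model refit F
  set.seed(40)
  M <- matrix(rnorm(200 * 5), 200, 5)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  y <- drop(Q %*% c(2, -1, 0.5, 0.3, -0.2)) + rnorm(200, sd = 0.5)
  fit <- fused_lasso(Q, y, n_bins = 1, lambda1 = 0, lambda2 = 0)
  n <- 200
  for (j in 1:5) {
    rec <- f_test_tf(fit, Q, y, j)
    red <- lm.fit(cbind(1, Q[, -j]), y)
    rss0_refit <- sum(red$residuals^2)
    f_refit <- ((rss0_refit - fit$rss) / 1) / (fit$rss / (n - 5 - 1))
    expect_equal(rec$f_stat, f_refit, tolerance = 1e-6)
  }

  # general (correlated) design: zero-out F is at least the refit F
  X <- matrix(runif(150 * 4), 150, 4)
  X[, 2] <- X[, 1] * 0.7 + X[, 2] * 0.3
  y2 <- drop(X %*% c(1, 1, 0.5, -0.5)) + rnorm(150, sd = 0.4)
  fit2 <- fused_lasso(X, y2, n_bins = 1, lambda1 = 0, lambda2 = 0)
  for (j in 1:4) {
    rec <- f_test_tf(fit2, X, y2, j)
    red <- lm.fit(cbind(1, X[, -j]), y2)
    f_refit <- ((sum(red$residuals^2) - fit2$rss) / 1) /
      (fit2$rss / (150 - 4 - 1))
    expect_gte(rec$f_stat + 1e-9, f_refit)
  }
})

test_that("zeroed TFs are untested and zeroing never lowers the RSS", {
  set.seed(42)
  X <- matrix(runif(120 * 20), 120, 20)
  y <- drop(X %*% c(rep(1, 5), rep(0, 15))) + rnorm(120, sd = 0.3)
  fit <- fused_lasso(X, y, n_bins = 5, lambda1 = 2, lambda2 = 1)
  at <- tf_association(fit, X, y)
  expect_equal(nrow(at), 4)
  # a TF with all-zero coefficients: identical models, F = 0, p = 1
  zeroed <- vapply(1:4, function(t) {
    all(abs(fit$beta[((t - 1) * 5 + 1):(t * 5)]) < 1e-12)
  }, TRUE)
  if (any(zeroed)) {
    expect_true(all(at$untested[zeroed]))
    expect_true(all(at$p_value[zeroed] == 1))
    expect_true(all(at$f_stat[zeroed] == 0))
  }
  # prediction with coefficients removed from an optimized fit cannot improve
  expect_true(all(at$rss0 >= fit$rss - 1e-9))
  expect_true(all(at$p_value >= 0 & at$p_value <= 1))
  # p decreases as F increases at fixed dfs
  expect_true(all(diff(pf(c(1, 5, 20), 2, 100, lower.tail = FALSE)) < 0))
})

test_that("ranking keeps the lowest p-values below alpha, at most top", {
  rec <- data.frame(tf_name = paste0("TF", 1:15),
                    coef_sum = seq(1.5, 0.1, length.out = 15),
                    sign = "positive",
                    p_value = c(seq(1e-6, 4e-3, length.out = 12),
                                0.2, 0.5, 0.9),
                    untested = FALSE)
  top <- rank_associations(rec, alpha = 0.005, top = 10)
  expect_equal(nrow(top), 10)
  expect_true(all(diff(top$p_value) >= 0))
  expect_equal(top$rank, 1:10)

  few <- rec[c(1:3, 13:15), ]
  expect_equal(nrow(rank_associations(few, alpha = 0.005)), 3)
  none <- rec[13:15, ]
  expect_equal(nrow(rank_associations(none, alpha = 0.005)), 0)

  # ties on p: larger |coef_sum| first, then name
  tie <- data.frame(tf_name = c("TFb", "TFa", "TFc"), coef_sum = c(1, -2, 1),
                    sign = "positive", p_value = rep(1e-4, 3),
                    untested = FALSE)
  expect_equal(rank_associations(tie)$tf_name, c("TFa", "TFb", "TFc"))
})

test_that("coefficient profiles expose block structure and planted steps", {
  set.seed(44)
  X <- matrix(runif(300 * 30), 300, 30)
  beta_true <- c(rep(2, 3), rep(0, 7), rep(0, 20)) # early-bin step on TF1
  y <- drop(X %*% beta_true) + rnorm(300, sd = 0.1)
  fit <- fused_lasso(X, y, n_bins = 10, lambda1 = 0.05, lambda2 = 0.5)
  pr <- coefficient_profile(fit, "TF1")
  expect_length(pr$coefficients, 10)
  # elevated early bins relative to late bins
  expect_gt(mean(pr$coefficients[1:3]), mean(pr$coefficients[4:10]) + 0.5)
  # a zero TF gives an all-zero profile
  pr3 <- coefficient_profile(fit, 3)
  if (all(abs(pr3$coefficients) < 1e-10)) {
    expect_equal(unname(pr3$coefficients), rep(0, 10))
    expect_false(any(pr3$blocks$nonzero))
  }
  # fully fused TF: single block
  fitf <- fused_lasso(X, y, n_bins = 10, lambda1 = 0, lambda2 = 1e5)
  prf <- coefficient_profile(fitf, 1)
  expect_equal(nrow(prf$blocks), 1)
  expect_error(coefficient_profile(fit, "TF99"), "unknown TF")
})

test_that("planted TFs rank above null TFs and keep their sign", {
  hits <- 0; signs_ok <- 0; runs <- 5
  for (s in seq_len(runs)) {
    cfg <- small_synth(seed = 100 + s, n_genes = 400, n_tfs = 8,
                       noise_sd = 0.15)
    ds <- generate_dataset(cfg)
    idx <- which(ds$truth$label == "poor")
    Xn <- normalize_log_unit(ds$tf_raw[idx, , drop = FALSE])
    yn <- normalize_log_unit(ds$hm_raw[idx, , drop = FALSE])[, 1]
    sel <- select_penalties(Xn, yn, n_bins = 10, gamma_grid = c(0, 0.1, 1),
                            n_lambda2 = 6, seed = s)
    fit <- fused_lasso(Xn, yn, n_bins = 10, lambda1 = sel$lambda1,
                       lambda2 = sel$lambda2)
    at <- tf_association(fit, Xn, yn)
    ranks <- rank(at$p_value)
    planted <- c(1, 3) # poor class: TF1 (negative), TF3 (positive)
    if (median(ranks[planted]) < median(ranks[-planted])) hits <- hits + 1
    if (at$sign[1] == "negative" && at$sign[3] == "positive") {
      signs_ok <- signs_ok + 1
    }
  }
  expect_gte(hits, runs - 1)
  expect_gte(signs_ok, runs - 1)
})
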