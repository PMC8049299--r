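# shared fixture builders (everything generated in code)

small_synth <- function(seed = 1, n_genes = 250, n_tfs = 6, noise_sd = 0.1,
                        planted = list(HM1 = list(
                          rich = list(`1` = rep(1, 10)),
                          poor = list(`1` = rep(-1, 10), `3` = rep(1, 10))))) {
  synthetic_config(n_genes = n_genes, n_tfs = n_tfs, n_bins = 10,
                   planted = planted, noise_sd = noise_sd, seed = seed)
}

random_instance <- function(seed, n_max = 30, p_choices = list(c(2, 3), c(3, 4),
                                                               c(2, 6), c(1, 8),
                                                               c(4, 3))) {
  set.seed(seed)
  mk <- p_choices[[sample.int(length(p_choices), 1)]]
  m <- mk[1]; k <- mk[2]
  n <- sample(10:n_max, 1)
  X <- matrix(runif(n * m * k), n, m * k)
  beta_true <- numeric(m * k)
  beta_true[sample.int(m * k, 3)] <- rnorm(3, 0, 2)
  y <- drop(X %*% beta_true) + rnorm(n, sd = 0.3)
  lambda2 <- 10^runif(1, -2, 0.7)
  lambda1 <- lambda2 * sample(c(0, 0.1, 1, 3), 1)
  list(X = X, y = y, k = k, m = m, lambda1 = lambda1, lambda2 = lambda2)
}
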