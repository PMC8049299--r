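# deterministic balanced fold assignment
.fold_ids <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

# correlation that degrades to 0 (no measurable linear association) instead of
# NA when either side is constant, so null models report 0 rather than fail
.safe_cor <- function(a, b, method = "pearson") {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b, method = method)
}

#' Default gamma grid for penalty selection
#'
#' `gamma = lambda1 / lambda2` controls the sparsity-to-fusion balance:
#' `gamma = 0` applies fusion only. The default grid is
#' `{0} U {10^i | i = -5, ..., 5}`.
#' @return Numeric vector of gamma values.
#' @export
default_gamma_grid <- function() c(0, 10^(-5:5))

# smallest lambda2 (at gamma = 0) fusing every chain to a single block,
# found by doubling search
.lambda2_max <- function(design, k, tol = 1e-7, max_iter = 5000L) {
  if (k == 1L) return(max(abs(design$b), 1e-8)) # no fusion possible; scale only
  m <- design$p %/% k
  lam <- max(abs(design$b), .Machine$double.eps) * 1e-4
  beta <- numeric(design$p)
  fully_fused <- function(beta) {
    bm <- matrix(beta, nrow = k)
    rng <- apply(bm, 2L, function(v) diff(range(v)))
    all(rng <= 1e-6 * max(1, max(abs(beta))))
  }
  for (i in 1:60) {
    fit <- .fused_fit_core(design, k, 0, lam, beta_init = beta, tol = tol,
                           max_iter = max_iter)
    beta <- fit$beta
    if (fully_fused(beta)) return(lam)
    lam <- lam * 2
  }
  lam
}

#' Select fused-LASSO penalties by inner cross-validation
#'
#' Grid search over `(gamma, lambda2)` minimizing the mean held-out residual
#' sum of squares across `inner_folds` folds, with `lambda1 = gamma * lambda2`.
#' The `lambda2` grid is geometric, from the smallest value fusing all chains
#' (found by doubling search at `gamma = 0`) down by `lambda2_min_ratio`.
#' Ties are broken towards the more regularized model (larger `lambda2`, then
#' larger `gamma`).
#'
#' @inheritParams fused_lasso
#' @param gamma_grid Ratios `lambda1 / lambda2` to explore (see
#'   [default_gamma_grid()]).
#' @param inner_folds Number of folds used for selection.
#' @param n_lambda2 Number of geometric `lambda2` grid points.
#' @param lambda2_min_ratio Ratio of the smallest to the largest `lambda2`.
#' @param seed Integer seed controlling the fold assignment.
#' @param cv_tol,cv_max_iter Solver tolerance/iteration cap used for the many
#'   grid fits (looser than the final fit for speed).
#' @return List with `gamma`, `lambda2`, `lambda1`, the `lambda2_grid`, the
#'   `gamma_grid` and `mean_rss` (matrix gamma x lambda2 of mean held-out RSS).
#' @export
select_penalties <- function(X, y, n_bins = 10,
                             gamma_grid = default_gamma_grid(),
                             inner_folds = 3, n_lambda2 = 30,
                             lambda2_min_ratio = 1e-5, seed = 1,
                             cv_tol = 1e-8, cv_max_iter = 5000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < inner_folds) stop("fewer genes than folds")
  k <- as.integer(n_bins)

  full_design <- .make_design(X, y)
  l2max <- .lambda2_max(full_design, k)
  l2grid <- exp(seq(log(l2max), log(l2max * lambda2_min_ratio),
                    length.out = n_lambda2))

  ids <- .fold_ids(n, inner_folds, seed)
  rss_sum <- matrix(0, length(gamma_grid), n_lambda2)
  for (f in seq_len(inner_folds)) {
    tr <- ids != f
    des <- .make_design(X[tr, , drop = FALSE], y[tr])
    Xv <- X[!tr, , drop = FALSE]
    yv <- y[!tr]
    for (gi in seq_along(gamma_grid)) {
      g <- gamma_grid[gi]
      beta <- numeric(ncol(X))
      for (li in seq_len(n_lambda2)) { # descending lambda2, warm started
        l2 <- l2grid[li]
        fit <- .fused_fit_core(des, k, g * l2, l2, beta_init = beta,
                               tol = cv_tol, max_iter = cv_max_iter,
                               polish = FALSE)
        beta <- fit$beta
        b0 <- des$ybar - sum(des$xbar * beta)
        pred <- drop(Xv %*% beta) + b0
        rss_sum[gi, li] <- rss_sum[gi, li] + sum((yv - pred)^2)
      }
    }
  }
  mean_rss <- rss_sum / inner_folds
  best <- min(mean_rss)
  tol <- 1e-12 * (1 + abs(best))
  # prefer larger lambda2, then larger gamma, among (near-)ties
  sel_gi <- NA_integer_; sel_li <- NA_integer_
  for (li in seq_len(n_lambda2)) { # l2grid is descending: first hit is largest
    for (gi in order(gamma_grid, decreasing = TRUE)) {
      if (mean_rss[gi, li] <= best + tol) {
        sel_gi <- gi; sel_li <- li
        break
      }
    }
    if (!is.na(sel_gi)) break
  }
  list(gamma = gamma_grid[sel_gi], lambda2 = l2grid[sel_li],
       lambda1 = gamma_grid[sel_gi] * l2grid[sel_li],
       lambda2_grid = l2grid, gamma_grid = gamma_grid, mean_rss = mean_rss)
}

#' Nested cross-validation for the chain fused LASSO
#'
#' Five-fold (by default) nested cross-validation: for each outer fold,
#' penalties are selected on the training part by [select_penalties()] (inner
#' folds, mean held-out RSS), the model is refitted on the outer-training set
#' and evaluated on the held-out fold (RSS, Pearson and Spearman correlation
#' between predictions and observed response). A final model is then fitted on
#' all genes at penalties selected on the full data set.
#'
#' @inheritParams select_penalties
#' @param outer_folds Number of outer folds (performance estimation).
#' @param ... Passed to [fused_lasso()] for the final fit.
#' @return Object of class `cv_fused_lasso`: list with `folds` (data frame:
#'   fold, gamma, lambda2, lambda1, rss, pearson, spearman, n_test),
#'   `final_fit` (a [fused_lasso] object), `selected` (final penalties),
#'   `seed` and `call`. Fold test sets partition the genes; the whole
#'   procedure is deterministic given `seed`.
#' @examples
#' set.seed(7)
#' X <- matrix(runif(150 * 10), 150, 10)
#' y <- X[, 1] + rnorm(150, sd = 0.1)
#' cv <- cv_fused_lasso(X, y, n_bins = 5, gamma_grid = c(0, 1),
#'                      n_lambda2 = 5, seed = 3)
#' cv$folds$pearson
#' @export
cv_fused_lasso <- function(X, y, n_bins = 10,
                           gamma_grid = default_gamma_grid(),
                           outer_folds = 5, inner_folds = 3, n_lambda2 = 30,
                           lambda2_min_ratio = 1e-5, seed = 1,
                           cv_tol = 1e-8, cv_max_iter = 5000L, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < outer_folds) stop("fewer genes than folds")
  ids <- .fold_ids(n, outer_folds, seed)
  rows <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- ids != f
    sel <- select_penalties(X[tr, , drop = FALSE], y[tr], n_bins = n_bins,
                            gamma_grid = gamma_grid,
                            inner_folds = inner_folds,
                            n_lambda2 = n_lambda2,
                            lambda2_min_ratio = lambda2_min_ratio,
                            seed = seed + f, cv_tol = cv_tol,
                            cv_max_iter = cv_max_iter)
    des <- .make_design(X[tr, , drop = FALSE], y[tr])
    fit <- .fused_fit_core(des, as.integer(n_bins), sel$lambda1, sel$lambda2,
                           tol = cv_tol, max_iter = cv_max_iter)
    b0 <- des$ybar - sum(des$xbar * fit$beta)
    pred <- drop(X[!tr, , drop = FALSE] %*% fit$beta) + b0
    yt <- y[!tr]
    rows[[f]] <- data.frame(
      fold = f, gamma = sel$gamma, lambda2 = sel$lambda2,
      lambda1 = sel$lambda1, rss = sum((yt - pred)^2),
      pearson = .safe_cor(pred, yt),
      spearman = .safe_cor(pred, yt, method = "spearman"),
      n_test = sum(!tr))
  }
  folds <- do.call(rbind, rows)
  sel <- select_penalties(X, y, n_bins = n_bins, gamma_grid = gamma_grid,
                          inner_folds = inner_folds, n_lambda2 = n_lambda2,
                          lambda2_min_ratio = lambda2_min_ratio,
                          seed = seed + outer_folds + 1L, cv_tol = cv_tol,
                          cv_max_iter = cv_max_iter)
  final_fit <- fused_lasso(X, y, n_bins = n_bins, lambda1 = sel$lambda1,
                           lambda2 = sel$lambda2, ...)
  structure(list(folds = folds, final_fit = final_fit,
                 selected = sel[c("gamma", "lambda2", "lambda1")],
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 seed = seed, call = match.call()),
            class = "cv_fused_lasso")
}

#' @export
print.cv_fused_lasso <- function(x, ...) {
  cat("Nested cross-validated chain fused LASSO (", x$outer_folds,
      " outer / ", x$inner_folds, " inner folds)\n", sep = "")
  cat(sprintf("  mean outer-fold Pearson = %.3f (range %.3f..%.3f)\n",
              mean(x$folds$pearson), min(x$folds$pearson),
              max(x$folds$pearson)))
  cat(sprintf("  final penalties: gamma = %.4g, lambda2 = %.4g\n",
              x$selected$gamma, x$selected$lambda2))
  invisible(x)
}

#' @export
summary.cv_fused_lasso <- function(object, ...) {
  print(object)
  cat("\nPer-fold performance:\n")
  print(object$folds, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.cv_fused_lasso <- function(x, ...) {
  plot(x$folds$fold, x$folds$pearson, pch = 16, ylim = c(-1, 1),
       xlab = "outer fold", ylab = "test Pearson correlation", ...)
  abline(h = mean(x$folds$pearson), lty = 2)
  invisible(x)
}
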