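#' Chain feature graph over TF bins
#'
#' Builds the feature graph used by the fusion penalty: within each
#' transcription factor, consecutive promoter bins are connected in a chain;
#' no edges join features of different TFs.
#'
#' @param m Number of transcription factors.
#' @param k Number of bins per TF.
#' @return An object of class `chain_graph` with elements `m`, `k` and
#'   `edges`, a two-column integer matrix of 1-based feature index pairs
#'   `(i, i+1)`; it has `m * (k - 1)` rows.
#' @examples
#' g <- chain_graph(3, 10)
#' nrow(g$edges) # 27
#' @export
chain_graph <- function(m, k) {
  stopifnot(length(m) == 1L, length(k) == 1L, m >= 1, k >= 1)
  m <- as.integer(m)
  k <- as.integer(k)
  if (k > 1L) {
    from <- rep((seq_len(m) - 1L) * k, each = k - 1L) + seq_len(k - 1L)
    edges <- cbind(from = from, to = from + 1L)
  } else {
    edges <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("from", "to")))
  }
  structure(list(m = m, k = k, edges = edges), class = "chain_graph")
}

#' Proximal operator of the chain fused-LASSO penalty
#'
#' Computes `argmin_b 1/2 ||b - z||^2 + lambda2 * sum_i |b_i - b_{i+1}| +
#' lambda1 * ||b||_1` where the total-variation term runs along each chain of
#' `n_bins` consecutive entries. For chain graphs this equals the exact
#' total-variation proximal map followed by elementwise soft-thresholding.
#'
#' @param z Numeric vector (length a multiple of `n_bins`).
#' @param lambda1 Nonnegative sparsity penalty.
#' @param lambda2 Nonnegative fusion penalty.
#' @param n_bins Chain length; defaults to `length(z)` (a single chain).
#' @return Numeric vector of the same length as `z`.
#' @examples
#' prox_chain_fused(c(1, 1), lambda1 = 0.5, lambda2 = 7) # c(0.5, 0.5)
#' @export
prox_chain_fused <- function(z, lambda1, lambda2, n_bins = length(z)) {
  stopifnot(is.numeric(z), all(is.finite(z)), length(z) >= 1L)
  if (!is.numeric(lambda1) || length(lambda1) != 1L || !is.finite(lambda1) ||
      lambda1 < 0) {
    stop("'lambda1' must be a single nonnegative number")
  }
  if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) ||
      lambda2 < 0) {
    stop("'lambda2' must be a single nonnegative number")
  }
  if (length(z) %% n_bins != 0L) {
    stop("length(z) must be a multiple of 'n_bins'")
  }
  out <- .prox_chain_cpp(as.numeric(z), lambda1, lambda2, as.integer(n_bins))
  as.numeric(out)
}

# Centered design bundle reused across penalty grid points.
.make_design <- function(X, y) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar, "-")
  ybar <- mean(y)
  yc <- y - ybar
  G <- crossprod(Xc)
  b <- drop(crossprod(Xc, yc))
  ev <- tryCatch(eigen(G, symmetric = TRUE, only.values = TRUE)$values[1L],
                 error = function(e) sum(diag(G)))
  L <- 2 * max(ev, .Machine$double.eps)
  list(G = G, b = b, yty = sum(yc^2), L = L, xbar = xbar, ybar = ybar,
       n = nrow(X), p = ncol(X))
}

# Active-pattern refinement: given the block/zero/sign pattern of a
# near-optimal beta, solve the implied stationarity system exactly and accept
# the solution only if it preserves the pattern and lowers the objective.
.polish_beta <- function(beta, design, k, lambda1, lambda2, obj_current) {
  p <- length(beta)
  m <- p %/% k
  amax <- max(abs(beta))
  if (amax == 0) return(NULL)
  tol <- 1e-6 * amax

  bid <- integer(p)
  nb <- 0L
  for (t in seq_len(m)) {
    idx <- ((t - 1L) * k + 1L):(t * k)
    nb <- nb + 1L
    bid[idx[1L]] <- nb
    if (k > 1L) {
      for (j in idx[-1L]) {
        if (abs(beta[j] - beta[j - 1L]) > tol) nb <- nb + 1L
        bid[j] <- nb
      }
    }
  }
  sizes <- tabulate(bid, nb)
  bval <- drop(rowsum(beta, bid)) / sizes
  free <- abs(bval) > tol
  if (!any(free)) return(NULL)
  sgn <- sign(bval)

  # boundary sign bookkeeping (within-chain boundaries only)
  w <- numeric(nb)
  chain_of <- rep(seq_len(m), each = k)
  first_of_block <- match(seq_len(nb), bid)
  if (nb >= 2L) for (b2 in 2L:nb) {
    j <- first_of_block[b2]
    if (j > 1L && chain_of[j] == chain_of[j - 1L]) {
      b1 <- bid[j - 1L]
      d <- sign(bval[b1] - bval[b2])
      w[b1] <- w[b1] + lambda2 * d
      w[b2] <- w[b2] - lambda2 * d
    }
  }

  freeids <- which(free)
  nf <- length(freeids)
  Bf <- matrix(0, p, nf)
  Bf[cbind(seq_len(p), match(bid, freeids))[free[bid], , drop = FALSE]] <- 1
  A <- 2 * crossprod(Bf, design$G %*% Bf)
  rhs <- 2 * drop(crossprod(Bf, design$b)) -
    lambda1 * sizes[freeids] * sgn[freeids] - w[freeids]
  cnew <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(cnew) || any(!is.finite(cnew))) return(NULL)
  if (any(sign(cnew) != sgn[freeids])) return(NULL)

  vnew <- numeric(nb)
  vnew[freeids] <- cnew
  # pattern check: every boundary keeps its difference sign
  if (nb >= 2L) for (b2 in 2L:nb) {
    j <- first_of_block[b2]
    if (j > 1L && chain_of[j] == chain_of[j - 1L]) {
      b1 <- bid[j - 1L]
      d <- sign(bval[b1] - bval[b2])
      if (sign(vnew[b1] - vnew[b2]) != d) return(NULL)
    }
  }
  beta_new <- vnew[bid]
  obj_new <- .fused_objective(beta_new, design, k, lambda1, lambda2)
  if (obj_new <= obj_current + 1e-12 * (1 + abs(obj_current))) {
    list(beta = beta_new, objective = obj_new)
  } else {
    NULL
  }
}

.fused_penalty <- function(beta, k, lambda1, lambda2) {
  m <- length(beta) %/% k
  tv <- 0
  if (k > 1L) {
    bm <- matrix(beta, nrow = k)
    tv <- sum(abs(bm[-1L, , drop = FALSE] - bm[-k, , drop = FALSE]))
  }
  lambda1 * sum(abs(beta)) + lambda2 * tv
}

.fused_objective <- function(beta, design, k, lambda1, lambda2) {
  design$yty - 2 * sum(design$b * beta) + drop(crossprod(beta, design$G %*% beta)) +
    .fused_penalty(beta, k, lambda1, lambda2)
}

# Core solver on a prebuilt design; returns centered-problem solution.
.fused_fit_core <- function(design, k, lambda1, lambda2, beta_init = NULL,
                            tol = 1e-9, max_iter = 20000L, polish = TRUE) {
  p <- design$p
  if (is.null(beta_init)) beta_init <- numeric(p)
  res <- .fista_fused_cpp(design$G, design$b, design$yty, as.integer(k),
                          lambda1, lambda2, as.numeric(beta_init), design$L,
                          tol, as.integer(max_iter))
  beta <- as.numeric(res$beta)
  obj <- res$objective
  if (polish) {
    pol <- .polish_beta(beta, design, k, lambda1, lambda2, obj)
    if (!is.null(pol)) {
      beta <- pol$beta
      obj <- pol$objective
    }
  }
  list(beta = beta, objective = obj, iterations = res$iterations,
       converged = isTRUE(res$converged))
}

#' Fit a sparse fused regression of one histone mark on binned TF signals
#'
#' Minimizes the penalized least-squares objective
#' \deqn{\|y - \beta_0 - X\beta\|_2^2 + \lambda_1 \|\beta\|_1 +
#'   \lambda_2 \sum_{(i,j) \in E} |\beta_i - \beta_j|}
#' where the edge set \eqn{E} joins adjacent promoter bins within each TF
#' ([chain_graph]). The intercept is unpenalized and handled by centering.
#' Optimization is accelerated proximal gradient descent (FISTA with a
#' function-value restart) using the exact chain proximal operator
#' ([prox_chain_fused]), followed by an exact refinement step on the detected
#' block pattern.
#'
#' The quadratic term is an unscaled sum of squares; all closed-form special
#' cases quoted in the documentation and tests use this scaling (for an
#' orthonormal centered design and `lambda2 = 0` the solution is the
#' soft-threshold of `t(X) %*% y` at `lambda1 / 2`).
#'
#' @param X Numeric matrix, genes in rows, `m * n_bins` feature columns
#'   ordered TF-major (TF1 bin1..bink, TF2 bin1..bink, ...). Typically the
#'   log-unit normalized bin signals from [normalize_log_unit()].
#' @param y Numeric response vector (window-mean HM signal per gene).
#' @param n_bins Bins per TF (chain length), default 10.
#' @param lambda1 Nonnegative sparsity penalty \eqn{\lambda_1}.
#' @param lambda2 Nonnegative fusion penalty \eqn{\lambda_2}.
#' @param tf_names Optional character vector of TF names (length
#'   `ncol(X) / n_bins`); defaults to names parsed from
#'   `colnames(X)` (`"name:bin"`) or `TF1..TFm`.
#' @param tol Convergence threshold on the relative objective decrease.
#' @param max_iter Maximum number of proximal-gradient iterations; hitting it
#'   flags the fit as non-converged (with a warning).
#' @param beta_init Optional warm-start coefficient vector.
#' @param polish Logical; run the exact block-pattern refinement (default
#'   `TRUE`).
#' @param block_tol Relative tolerance (scaled by `max(abs(beta))`) used to
#'   decide fusion equality and nonzeroness of blocks.
#' @return An object of class `fused_lasso`: a list with components `beta0`,
#'   `beta` (named coefficient vector), `lambda1`, `lambda2`, `gamma`
#'   (`lambda1 / lambda2`), `rss`, `objective`, `blocks` (data frame of fused
#'   blocks with columns `tf`, `start`, `end`, `value`), `df` (number of
#'   nonzero blocks), `fitted`, `y`, `converged`, `iterations`, `n_bins`,
#'   `tf_names`, `block_tol` and `call`. Methods: [print()], [summary()],
#'   [coef()], [predict()], [fitted()], [residuals()], [plot()].
#' @seealso [cv_fused_lasso()] for penalty selection by nested
#'   cross-validation, [tf_association()] for the F-test ranking.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(200 * 20), 200, 20)
#' y <- rowMeans(X[, 1:10]) + rnorm(200, sd = 0.05)
#' fit <- fused_lasso(X, y, n_bins = 10, lambda1 = 0.5, lambda2 = 2)
#' fit$df
#' @export
fused_lasso <- function(X, y, n_bins = 10, lambda1 = 0, lambda2 = 0,
                        tf_names = NULL, tol = 1e-9, max_iter = 20000L,
                        beta_init = NULL, polish = TRUE, block_tol = 1e-6) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) stop("'X' must be finite numeric")
  if (!is.numeric(y) || !all(is.finite(y))) stop("'y' must be finite numeric")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (ncol(X) %% n_bins != 0L) stop("ncol(X) must be a multiple of 'n_bins'")
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative")
  n_bins <- as.integer(n_bins)
  m <- ncol(X) %/% n_bins
  tf_names <- .resolve_tf_names(tf_names, colnames(X), m, n_bins)

  design <- .make_design(X, y)
  core <- .fused_fit_core(design, n_bins, lambda1, lambda2,
                          beta_init = beta_init, tol = tol,
                          max_iter = max_iter, polish = polish)
  if (!core$converged) {
    warning("fused_lasso did not converge in ", max_iter,
            " iterations; result is flagged")
  }
  beta <- core$beta
  names(beta) <- if (!is.null(colnames(X))) colnames(X) else
    paste0(rep(tf_names, each = n_bins), ":", rep(seq_len(n_bins), m))
  beta0 <- design$ybar - sum(design$xbar * beta)
  fitted <- drop(X %*% beta) + beta0
  rss <- sum((y - fitted)^2)
  blocks <- fused_blocks(beta, n_bins, tol = block_tol * max(abs(beta), 0),
                         tf_names = tf_names)
  structure(list(
    beta0 = beta0, beta = beta, lambda1 = lambda1, lambda2 = lambda2,
    gamma = if (lambda2 > 0) lambda1 / lambda2 else if (lambda1 == 0) 0 else Inf,
    rss = rss, objective = core$objective, blocks = blocks,
    df = sum(blocks$nonzero), fitted = fitted, y = y,
    converged = core$converged, iterations = core$iterations,
    n_bins = n_bins, n_tfs = m, tf_names = tf_names, block_tol = block_tol,
    call = match.call()
  ), class = "fused_lasso")
}

.resolve_tf_names <- function(tf_names, cn, m, k) {
  if (!is.null(tf_names)) {
    stopifnot(length(tf_names) == m)
    return(as.character(tf_names))
  }
  if (!is.null(cn)) {
    cand <- sub(":[0-9]+$", "", cn[seq(1L, m * k, by = k)])
    if (anyDuplicated(cand) == 0L) return(cand)
  }
  paste0("TF", seq_len(m))
}

#' Fused block structure of a coefficient vector
#'
#' Decomposes a coefficient vector into maximal runs of (numerically) equal
#' values within each TF chain.
#'
#' @param beta Numeric coefficient vector of length `m * n_bins`.
#' @param n_bins Bins per TF chain.
#' @param tol Absolute tolerance for equality/nonzeroness; default
#'   `1e-6 * max(abs(beta))`.
#' @param tf_names Optional TF names.
#' @return Data frame with one row per block: `tf`, `start`, `end` (1-based
#'   bin range in gene orientation), `value` (mean of the run) and `nonzero`.
#' @export
fused_blocks <- function(beta, n_bins, tol = NULL, tf_names = NULL) {
  stopifnot(is.numeric(beta), length(beta) %% n_bins == 0L)
  k <- as.integer(n_bins)
  m <- length(beta) %/% k
  if (is.null(tol)) tol <- 1e-6 * max(abs(beta), 0)
  if (is.null(tf_names)) tf_names <- paste0("TF", seq_len(m))
  out <- vector("list", m)
  for (t in seq_len(m)) {
    v <- beta[((t - 1L) * k + 1L):(t * k)]
    brk <- if (k > 1L) which(abs(diff(v)) > tol) else integer(0)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, k)
    vals <- vapply(seq_along(starts),
                   function(i) mean(v[starts[i]:ends[i]]), 0)
    out[[t]] <- data.frame(tf = tf_names[t], start = starts, end = ends,
                           value = vals, nonzero = abs(vals) > tol,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fused degrees of freedom
#'
#' Degrees of freedom of a fused coefficient vector: the number of nonzero
#' blocks, where a block is a maximal run of coefficients with (numerically)
#' equal value within a TF chain. For `n_bins = 1` this reduces to the count
#' of nonzero coefficients (the LASSO df).
#'
#' @inheritParams fused_blocks
#' @return Integer count of nonzero blocks.
#' @examples
#' count_df(c(0, 0, 0.4, 0.4, 0.4, -0.2, 0, 0.7, 0.7, 0), n_bins = 10) # 3
#' @export
count_df <- function(beta, n_bins, tol = NULL) {
  sum(fused_blocks(beta, n_bins, tol = tol)$nonzero)
}

#' @export
print.fused_lasso <- function(x, ...) {
  cat("Chain fused-LASSO fit:", x$n_tfs, "TFs x", x$n_bins, "bins,",
      length(x$y), "genes\n")
  cat(sprintf("  lambda1 = %.4g, lambda2 = %.4g (gamma = %.4g)\n",
              x$lambda1, x$lambda2, x$gamma))
  cat(sprintf("  RSS = %.6g, df (nonzero blocks) = %d, converged: %s\n",
              x$rss, x$df, x$converged))
  invisible(x)
}

#' @export
coef.fused_lasso <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' @export
fitted.fused_lasso <- function(object, ...) object$fitted

#' @export
residuals.fused_lasso <- function(object, ...) object$y - object$fitted

#' @export
predict.fused_lasso <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    stop("'newdata' must have ", length(object$beta), " columns")
  }
  drop(newdata %*% object$beta) + object$beta0
}

#' @export
summary.fused_lasso <- function(object, ...) {
  k <- object$n_bins
  sums <- drop(rowsum(object$beta, rep(seq_len(object$n_tfs), each = k)))
  tf <- data.frame(tf = object$tf_names, coef_sum = sums,
                   nonzero_blocks = tapply(object$blocks$nonzero,
                                           factor(object$blocks$tf,
                                                  levels = object$tf_names),
                                           sum),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fit = object, tf_summary = tf[order(-abs(tf$coef_sum)), ]),
            class = "summary.fused_lasso")
}

#' @export
print.summary.fused_lasso <- function(x, ...) {
  print(x$fit)
  cat("\nPer-TF summed coefficients (largest first):\n")
  print(head(x$tf_summary, 10), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fused_lasso <- function(x, tfs = NULL, ...) {
  k <- x$n_bins
  bm <- matrix(x$beta, nrow = k)
  colnames(bm) <- x$tf_names
  if (is.null(tfs)) {
    sums <- colSums(abs(bm))
    tfs <- x$tf_names[order(-sums)][seq_len(min(5L, x$n_tfs))]
  }
  cols <- hcl.colors(length(tfs), "Dark 3")
  matplot(seq_len(k), bm[, tfs, drop = FALSE], type = "b", pch = 16,
          lty = 1, col = cols, xlab = "promoter bin (upstream to downstream)",
          ylab = "coefficient", ...)
  abline(h = 0, lty = 3)
  legend("topright", legend = tfs, col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}
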