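#' Residuals of an OLS regression on conditioning variables
#'
#' Regresses `target` on `Z` (with intercept) by ordinary least squares and
#' returns the residuals; with empty `Z` this is plain centering. Linearly
#' dependent columns of `Z` are dropped (QR rank detection) with a warning.
#'
#' @param target Numeric vector.
#' @param Z Numeric matrix of conditioning variables (or `NULL`).
#' @return Residual vector of the same length.
#' @export
residualize <- function(target, Z = NULL) {
  stopifnot(is.numeric(target), all(is.finite(target)))
  if (is.null(Z) || NCOL(Z) == 0L) return(target - mean(target))
  Z <- as.matrix(Z)
  if (nrow(Z) != length(target)) stop("rows of 'Z' must align with 'target'")
  M <- cbind(`(Intercept)` = 1, Z)
  fit <- lm.fit(M, target)
  if (fit$rank < ncol(M)) {
    warning("dropping ", ncol(M) - fit$rank,
            " linearly dependent conditioning column(s)")
  }
  unname(fit$residuals)
}

#' Partial correlation of two signals given conditioning variables
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on `Z` — the association between two histone marks net of all
#' other marks.
#'
#' @param x,y Numeric vectors.
#' @param Z Conditioning matrix (may be `NULL`: plain correlation of the
#'   centered vectors).
#' @return Scalar partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  if (var(rx) <= 1e-12 * max(var(x), .Machine$double.eps) ||
      var(ry) <= 1e-12 * max(var(y), .Machine$double.eps)) {
    stop("zero residual variance: degenerate conditioning")
  }
  cor(rx, ry)
}

#' Permutation p-value for a (partial) correlation
#'
#' Permutes the first residual vector `n_perm` times (the second is kept
#' fixed) and compares the permuted correlations with the observed one. The
#' default is two-sided on `|rho|` with the add-one correction
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`; `alternative =
#' "greater"` restores the literal one-sided rule and `add_one = FALSE` the
#' raw-count estimator `#{...} / n_perm`.
#'
#' @param rx,ry Residual vectors (equal length, at least 3).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param add_one Use the add-one correction (default `TRUE`).
#' @return The permutation p-value, with the observed correlation attached as
#'   attribute `"observed"`.
#' @export
permutation_pvalue <- function(rx, ry, n_perm = 10000, seed = 1,
                               alternative = c("two.sided", "greater"),
                               add_one = TRUE) {
  alternative <- match.arg(alternative)
  n <- length(rx)
  stopifnot(length(ry) == n, n >= 3L)
  u <- rx - mean(rx)
  v <- ry - mean(ry)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero residual variance")
  u <- u / nu
  v <- v / nv
  obs <- sum(u * v)
  set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  perm <- drop(crossprod(matrix(u[idx], n), v))
  eps <- 1e-12
  hits <- if (alternative == "two.sided") sum(abs(perm) >= abs(obs) - eps)
          else sum(perm >= obs - eps)
  p <- if (add_one) (1 + hits) / (n_perm + 1) else hits / n_perm
  attr(p, "observed") <- obs
  p
}

#' Pairwise partial correlations between histone marks, per CpG class
#'
#' For every unordered pair of marks `(X, Y)`, the partial correlation given
#' all remaining marks is computed ([partial_correlation()]) together with a
#' permutation p-value ([permutation_pvalue()]); p-values are
#' Bonferroni-corrected over the `choose(n_hm, 2)` pairs within each class
#' and thresholded at `alpha`. With class labels the analysis is run
#' separately on the CpG-poor and CpG-rich genes.
#'
#' @param hm Numeric genes x marks matrix (window-mean signals, on the same
#'   normalization as the model responses), with column names.
#' @param labels Optional factor of per-gene class labels (`poor`/`rich`);
#'   `NULL` analyses all genes as one class.
#' @param alpha Significance level on the Bonferroni-corrected p-values
#'   (default 0.01).
#' @param n_perm Permutations per pair (default 10000).
#' @param seed Integer seed; each (class, pair) uses the documented derived
#'   seed `seed + 1000 * class_index + pair_index`.
#' @param alternative,add_one Passed to [permutation_pvalue()].
#' @return For `labels = NULL` an object of class `partial_correlation_set`;
#'   otherwise a named list of such objects (one per class). Each holds
#'   `hm_names`, `class_label`, `rho` (symmetric, unit diagonal), `p_raw`,
#'   `p_bonf`, `significant` (logical mask at `alpha`), `n_perm`, `n_genes`,
#'   `alpha`, `seed`.
#' @export
pc_matrix <- function(hm, labels = NULL, alpha = 0.01, n_perm = 10000,
                      seed = 1, alternative = c("two.sided", "greater"),
                      add_one = TRUE) {
  alternative <- match.arg(alternative)
  hm <- as.matrix(hm)
  stopifnot(alpha > 0, alpha < 1, ncol(hm) >= 2L)
  if (is.null(colnames(hm))) colnames(hm) <- paste0("HM", seq_len(ncol(hm)))
  if (is.null(labels)) {
    return(.pc_one_class(hm, "all", alpha, n_perm, seed, 1L, alternative,
                         add_one))
  }
  labels <- factor(labels)
  if (length(labels) != nrow(hm)) stop("labels must align with rows of 'hm'")
  out <- lapply(seq_along(levels(labels)), function(ci) {
    cl <- levels(labels)[ci]
    .pc_one_class(hm[labels == cl, , drop = FALSE], cl, alpha, n_perm, seed,
                  ci, alternative, add_one)
  })
  names(out) <- levels(labels)
  out
}

.pc_one_class <- function(hm, class_label, alpha, n_perm, seed, class_index,
                          alternative, add_one) {
  n_hm <- ncol(hm)
  if (nrow(hm) < n_hm + 2L) {
    stop("class '", class_label, "' has fewer genes (", nrow(hm),
         ") than required for conditioning (need >= ", n_hm + 2L, ")")
  }
  rho <- diag(1, n_hm)
  p_raw <- matrix(NA_real_, n_hm, n_hm)
  dimnames(rho) <- dimnames(p_raw) <- list(colnames(hm), colnames(hm))
  pairs <- utils::combn(n_hm, 2L)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    Z <- hm[, -c(i, j), drop = FALSE]
    rx <- residualize(hm[, i], Z)
    ry <- residualize(hm[, j], Z)
    if (var(rx) <= 0 || var(ry) <= 0) {
      stop("zero residual variance for pair ", colnames(hm)[i], "-",
           colnames(hm)[j])
    }
    r <- cor(rx, ry)
    p <- permutation_pvalue(rx, ry, n_perm = n_perm,
                            seed = seed + 1000L * class_index + q,
                            alternative = alternative, add_one = add_one)
    rho[i, j] <- rho[j, i] <- r
    p_raw[i, j] <- p_raw[j, i] <- as.numeric(p)
  }
  n_pairs <- ncol(pairs)
  p_bonf <- p_raw * n_pairs
  p_bonf[!is.na(p_bonf) & p_bonf > 1] <- 1
  significant <- !is.na(p_bonf) & p_bonf < alpha
  structure(list(hm_names = colnames(hm), class_label = class_label,
                 rho = rho, p_raw = p_raw, p_bonf = p_bonf,
                 significant = significant, n_pairs = n_pairs,
                 n_perm = n_perm, n_genes = nrow(hm), alpha = alpha,
                 seed = seed),
            class = "partial_correlation_set")
}

#' @export
print.partial_correlation_set <- function(x, ...) {
  cat("Partial correlations between", length(x$hm_names),
      "histone marks (class:", x$class_label, ";", x$n_genes, "genes)\n")
  cat("  ", x$n_pairs, " pairs, ", x$n_perm,
      " permutations each, Bonferroni alpha = ", x$alpha, "\n", sep = "")
  m <- format(round(x$rho, 3))
  m[upper.tri(m)][x$significant[upper.tri(x$significant)]] <-
    paste0(m[upper.tri(m)][x$significant[upper.tri(x$significant)]], "*")
  print(noquote(m))
  invisible(x)
}
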