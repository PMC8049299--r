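# nested-model F with block degrees of freedom:
# ((RSS0 - RSSfull) / df_num) / (RSSfull / df_den)
.f_stat <- function(rss0, rss_full, df_num, df_den) {
  (max(rss0 - rss_full, 0) / df_num) / (rss_full / df_den)
}

#' Approximate-refit F-test for one TF
#'
#' Tests whether a TF contributes to a fitted fused-LASSO model by zeroing
#' its `k` bin coefficients (no refit — retraining per TF would be
#' intractable) and comparing the resulting residual sum of squares
#' \eqn{RSS_0} with the full-model \eqn{RSS_{full}} through
#' \deqn{F = \frac{(RSS_0 - RSS_{full}) / (df_{full} - df_0)}
#'             {RSS_{full} / (N - df_{full} - 1)}}
#' where the degrees of freedom count nonzero fused blocks ([count_df()]).
#' A TF whose coefficients are entirely zero in the full model is returned
#' untested (`F = 0`, `p = 1`).
#'
#' @param fit A [fused_lasso] fit.
#' @param X,y The data the model was fitted on.
#' @param tf TF index or name.
#' @return One-row data frame: `tf_name`, `coef_sum` (sum of the TF's bin
#'   coefficients), `sign` (`positive`/`negative`/`zero` at the block
#'   tolerance), `rss0`, `f_stat`, `df_num`, `df_den`, `p_value`, `untested`.
#' @export
f_test_tf <- function(fit, X, y, tf) {
  stopifnot(inherits(fit, "fused_lasso"))
  X <- as.matrix(X)
  if (nrow(X) != length(y) || ncol(X) != length(fit$beta)) {
    stop("'X'/'y' do not match the fitted model")
  }
  if (!fit$converged) warning("testing a non-converged fit")
  tf_idx <- if (is.character(tf)) match(tf, fit$tf_names) else as.integer(tf)
  if (is.na(tf_idx) || tf_idx < 1L || tf_idx > fit$n_tfs) {
    stop("unknown TF: ", tf)
  }
  k <- fit$n_bins
  n <- nrow(X)
  abs_tol <- fit$block_tol * max(abs(fit$beta), 0)
  df_full <- fit$df
  df_den <- n - df_full - 1L
  if (df_den <= 0L) stop("nonpositive denominator degrees of freedom")
  rss_full <- fit$rss

  cols <- ((tf_idx - 1L) * k + 1L):(tf_idx * k)
  beta0v <- fit$beta
  beta0v[cols] <- 0
  pred0 <- drop(X %*% beta0v) + fit$beta0
  rss0 <- sum((y - pred0)^2)
  df0 <- count_df(beta0v, k, tol = abs_tol)
  df_num <- df_full - df0

  coef_sum <- sum(fit$beta[cols])
  sgn <- if (abs(coef_sum) <= abs_tol) "zero" else
    if (coef_sum > 0) "positive" else "negative"

  if (df_num <= 0L) {
    f_stat <- 0; p <- 1; untested <- TRUE; df_num <- 0L
  } else {
    f_stat <- .f_stat(rss0, rss_full, df_num, df_den)
    p <- pf(f_stat, df_num, df_den, lower.tail = FALSE)
    untested <- FALSE
  }
  data.frame(tf_name = fit$tf_names[tf_idx], coef_sum = coef_sum, sign = sgn,
             rss0 = rss0, f_stat = f_stat, df_num = df_num, df_den = df_den,
             p_value = p, untested = untested, stringsAsFactors = FALSE)
}

#' F-test association records for all TFs of a model
#'
#' Applies [f_test_tf()] to every TF of a fitted model.
#'
#' @inheritParams f_test_tf
#' @return Data frame of class `association_table` with one row per TF (see
#'   [f_test_tf()] for columns); attributes `n`, `df_full`, `rss_full`.
#' @seealso [rank_associations()]
#' @export
tf_association <- function(fit, X, y) {
  stopifnot(inherits(fit, "fused_lasso"))
  rows <- lapply(seq_len(fit$n_tfs), function(t) f_test_tf(fit, X, y, t))
  out <- do.call(rbind, rows)
  structure(out, n = nrow(as.matrix(X)), df_full = fit$df,
            rss_full = fit$rss,
            class = c("association_table", "data.frame"))
}

#' Rank significant TF associations
#'
#' Keeps the records with `p_value < alpha`, sorts ascending by p-value (ties
#' broken by `|coef_sum|` descending, then TF name) and truncates to the
#' `top` lowest — the "ten lowest p-values below alpha" reporting rule.
#'
#' @param records An [tf_association()] table (or compatible data frame).
#' @param alpha Significance cutoff (default 0.005).
#' @param top Maximum number of reported TFs (default 10).
#' @return The filtered, ranked table (possibly empty) with a `rank` column;
#'   attributes `alpha` and `top`.
#' @export
rank_associations <- function(records, alpha = 0.005, top = 10) {
  stopifnot(alpha > 0, alpha < 1, top >= 1)
  keep <- records$p_value < alpha & !records$untested
  out <- records[keep, , drop = FALSE]
  o <- order(out$p_value, -abs(out$coef_sum), out$tf_name)
  out <- out[o, , drop = FALSE]
  out <- head(out, top)
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  else out$rank <- integer(0)
  rownames(out) <- NULL
  structure(out, alpha = alpha, top = top,
            class = c("association_table", "data.frame"))
}

#' Per-bin coefficient profile of one TF
#'
#' Returns a TF's fitted coefficients across the promoter bins (gene
#' orientation) together with the fused block annotation — the data behind
#' coefficient heat maps showing positional deviation along the promoter.
#'
#' @inheritParams f_test_tf
#' @param tf TF index or name.
#' @return List with `tf_name`, `coefficients` (named `bin1..bink`) and
#'   `blocks` (rows of `fit$blocks` for this TF).
#' @export
coefficient_profile <- function(fit, tf) {
  stopifnot(inherits(fit, "fused_lasso"))
  tf_idx <- if (is.character(tf)) match(tf, fit$tf_names) else as.integer(tf)
  if (is.na(tf_idx) || tf_idx < 1L || tf_idx > fit$n_tfs) {
    stop("unknown TF: ", tf)
  }
  k <- fit$n_bins
  co <- fit$beta[((tf_idx - 1L) * k + 1L):(tf_idx * k)]
  names(co) <- paste0("bin", seq_len(k))
  blocks <- fit$blocks[fit$blocks$tf == fit$tf_names[tf_idx], , drop = FALSE]
  rownames(blocks) <- NULL
  list(tf_name = fit$tf_names[tf_idx], coefficients = co, blocks = blocks)
}

#' Presence/sign matrix of significant associations across models
#'
#' Condenses several ranked association tables into a TF x model matrix with
#' entries `+`, `-` or `.` (not significant), the usual cross-model summary
#' of signed TF-HM associations.
#'
#' @param tables Named list of [rank_associations()] results (names are model
#'   ids such as `"HM1_rich"`).
#' @param tf_names Optional row universe; defaults to the union of TFs seen.
#' @return Character matrix (TFs x models).
#' @export
association_sign_matrix <- function(tables, tf_names = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (is.null(tf_names)) {
    tf_names <- sort(unique(unlist(lapply(tables, function(t) t$tf_name))))
  }
  out <- matrix(".", length(tf_names), length(tables),
                dimnames = list(tf_names, names(tables)))
  for (mid in names(tables)) {
    t <- tables[[mid]]
    for (i in seq_len(nrow(t))) {
      out[t$tf_name[i], mid] <- if (t$sign[i] == "negative") "-" else "+"
    }
  }
  out
}
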