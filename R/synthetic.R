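#' Configuration for the synthetic promoter data generator
#'
#' Describes a simulated data set with the statistical structure the analysis
#' assumes: bimodal per-promoter CpG counts (two-Gaussian mixture, rounded and
#' truncated at zero), log-normal raw TF bin signals, and histone-modification
#' responses built as sparse, CpG-class-dependent linear combinations of the
#' log-unit normalized TF bins plus Gaussian noise. A single `seed` governs
#' all draws through a fixed sub-stream order: CpG counts use `seed`, the TF
#' matrix `seed + 1`, the response noise `seed + 2`, so each component can be
#' regenerated independently and bit-exactly.
#'
#' @param n_genes Number of genes (promoters), at least 2.
#' @param n_tfs Number of transcription factors `m`.
#' @param n_bins Bins per TF window `k` (default 10).
#' @param cpg_mixture List with numeric length-2 components `weight` (summing
#'   to 1), `mean` and `sd` (nonnegative; the component with the smaller mean
#'   is the CpG-poor class).
#' @param planted Planted association structure: a named list over histone
#'   marks; each mark is a list with elements `poor` and/or `rich`, each a
#'   named list mapping a TF index (as character) to a length-`n_bins`
#'   coefficient vector applied to that TF's normalized bins. `NULL` plants
#'   nothing (pure-noise responses). The default ([default_planted()]) plants
#'   class-dependent associations including a between-class sign flip and a
#'   class-exclusive TF.
#' @param noise_sd Response noise standard deviation; scalar or one value per
#'   histone mark. See [noise_sd_for_r2()] to target a signal-to-noise level.
#' @param background List `location`, `scale`: log-scale mean and sd of the
#'   raw TF signals (`exp` of Gaussian draws).
#' @param seed Integer seed.
#' @return Object of class `synthetic_config` (validated list).
#' @export
synthetic_config <- function(n_genes = 1000, n_tfs = 15, n_bins = 10,
                             cpg_mixture = list(weight = c(0.27, 0.73),
                                                mean = c(20, 60),
                                                sd = c(5, 8)),
                             planted = default_planted(n_tfs, n_bins),
                             noise_sd = 0.25,
                             background = list(location = 2, scale = 1),
                             seed = 1) {
  stopifnot(n_genes >= 2, n_tfs >= 1, n_bins >= 1)
  w <- cpg_mixture$weight
  if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("mixture component weights must be two nonnegative values summing to 1")
  }
  if (length(cpg_mixture$mean) != 2L || length(cpg_mixture$sd) != 2L) {
    stop("mixture 'mean' and 'sd' must each have two components")
  }
  if (any(cpg_mixture$sd < 0)) stop("mixture sd must be nonnegative")
  if (any(noise_sd < 0)) stop("'noise_sd' must be nonnegative")
  if (background$scale < 0) stop("background scale must be nonnegative")
  if (!is.null(planted)) {
    if (is.null(names(planted)) || any(names(planted) == "")) {
      stop("'planted' must be a named list over histone marks")
    }
    for (hm in names(planted)) {
      for (cl in names(planted[[hm]])) {
        if (!cl %in% c("poor", "rich")) {
          stop("planted classes must be 'poor' or 'rich'")
        }
        map <- planted[[hm]][[cl]]
        idx <- suppressWarnings(as.integer(names(map)))
        if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_tfs)) {
          stop("planted TF indices must be integers in 1..n_tfs")
        }
        for (v in map) {
          if (length(v) != n_bins || !all(is.finite(v))) {
            stop("planted coefficient vectors must be finite and of length n_bins")
          }
        }
      }
    }
  }
  n_hms <- if (is.null(planted)) 1L else length(planted)
  if (!length(noise_sd) %in% c(1L, n_hms)) {
    stop("'noise_sd' must be scalar or one value per histone mark")
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_bins = as.integer(n_bins), cpg_mixture = cpg_mixture,
                 planted = planted, noise_sd = noise_sd,
                 background = background, seed = as.integer(seed),
                 n_hms = n_hms,
                 hm_names = if (is.null(planted)) "HM1" else names(planted)),
            class = "synthetic_config")
}

#' Default planted association structure
#'
#' Plants, for three histone marks, sparse block-constant coefficient sets
#' that differ between CpG classes: TF1 switches sign between the rich and
#' poor class (for HM1 and HM2, so that the HM1-HM2 coupling flips sign
#' between classes), TF2 contributes an early-bin step in the rich class
#' only, TF3 is exclusive to the poor class, and TF4/TF5 act identically in
#' both classes.
#'
#' @param m Number of TFs (at least 5).
#' @param k Bins per TF.
#' @return Planted structure suitable for [synthetic_config()].
#' @export
default_planted <- function(m, k) {
  if (m < 5) stop("default planted structure needs at least 5 TFs")
  list(
    HM1 = list(rich = list(`1` = rep(1, k),
                           `2` = c(rep(1.5, min(3, k)), rep(0, max(0, k - 3)))),
               poor = list(`1` = rep(-1, k), `3` = rep(1, k))),
    HM2 = list(rich = list(`4` = rep(1, k), `1` = rep(0.8, k)),
               poor = list(`4` = rep(1, k), `1` = rep(0.8, k))),
    HM3 = list(rich = list(`5` = rep(1, k)), poor = list(`5` = rep(1, k)))
  )
}

#' Draw per-promoter CpG counts from the bimodal mixture
#'
#' Counts are drawn from the two-Gaussian mixture in
#' `config$cpg_mixture`, rounded to the nearest integer and truncated at 0.
#' The generating component is recorded as the true class label (the
#' component with the smaller mean is "poor").
#'
#' @param config A [synthetic_config()].
#' @return List with `counts` (integer vector), `component` (1/2 index of the
#'   generating component) and `label` (factor with levels `poor`, `rich`).
#' @export
generate_cpg_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mx <- config$cpg_mixture
  set.seed(config$seed)
  comp <- sample.int(2L, config$n_genes, replace = TRUE, prob = mx$weight)
  counts <- as.integer(pmax(0, round(rnorm(config$n_genes, mx$mean[comp],
                                           mx$sd[comp]))))
  poor_comp <- which.min(mx$mean)
  label <- factor(ifelse(comp == poor_comp, "poor", "rich"),
                  levels = c("poor", "rich"))
  list(counts = counts, component = comp, label = label)
}

#' Generate raw TF bin signals
#'
#' Entries are exponentials of Gaussian draws (log-normal, strictly
#' positive), emulating right-skewed accumulated ChIP-seq read counts.
#' Columns are ordered TF-major, bin-minor (`TF1:1 ... TF1:k, TF2:1, ...`).
#'
#' @param config A [synthetic_config()].
#' @return Numeric `n_genes x (n_tfs * n_bins)` matrix with gene rownames and
#'   `TF:bin` colnames.
#' @export
generate_tf_signals <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  m <- config$n_tfs
  k <- config$n_bins
  mat <- exp(matrix(rnorm(n * m * k, config$background$location,
                          config$background$scale), n, m * k))
  dimnames(mat) <- list(sprintf("g%05d", seq_len(n)),
                        paste0(rep(paste0("TF", seq_len(m)), each = k), ":",
                               rep(seq_len(k), m)))
  mat
}

#' Build histone-mark responses from planted coefficients
#'
#' For each gene the response is the planted linear combination of the
#' log-unit normalized TF bins of its CpG class (normalization computed per
#' class, the model's feature space) plus Gaussian noise, then shifted per
#' mark so the minimum is 0 (raw-signal semantics).
#'
#' @param tf_raw Raw TF matrix from [generate_tf_signals()].
#' @param cpg_labels Factor of per-gene class labels (`poor`/`rich`).
#' @param config A [synthetic_config()].
#' @return Numeric `n_genes x n_hms` response matrix; the noiseless signal
#'   (before shifting) is attached as attribute `"noiseless"`.
#' @export
generate_hm_response <- function(tf_raw, cpg_labels, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(tf_raw)
  k <- config$n_bins
  m <- ncol(tf_raw) %/% k
  if (length(cpg_labels) != n) stop("labels must align with tf_raw rows")
  cpg_labels <- factor(cpg_labels, levels = c("poor", "rich"))
  noise_sd <- rep_len(config$noise_sd, config$n_hms)

  signal <- matrix(0, n, config$n_hms,
                   dimnames = list(rownames(tf_raw), config$hm_names))
  for (cl in levels(cpg_labels)) {
    idx <- which(cpg_labels == cl)
    if (!length(idx)) next
    Xn <- normalize_log_unit(tf_raw[idx, , drop = FALSE])
    for (h in seq_len(config$n_hms)) {
      map <- if (is.null(config$planted)) NULL else config$planted[[h]][[cl]]
      if (is.null(map)) next
      for (nm in names(map)) {
        tf <- as.integer(nm)
        if (tf > m) stop("planted TF index exceeds the number of TFs")
        cols <- ((tf - 1L) * k + 1L):(tf * k)
        signal[idx, h] <- signal[idx, h] +
          drop(Xn[, cols, drop = FALSE] %*% map[[nm]])
      }
    }
  }
  set.seed(config$seed + 2L)
  noise <- matrix(rnorm(n * config$n_hms), n, config$n_hms)
  noise <- sweep(noise, 2L, noise_sd, "*")
  y <- signal + noise
  y <- sweep(y, 2L, apply(y, 2L, min), "-")
  attr(y, "noiseless") <- signal
  y
}

#' Generate a complete synthetic data set with ground truth
#'
#' Composes [generate_cpg_counts()], [generate_tf_signals()] and
#' [generate_hm_response()] under the config's documented seed sub-streams,
#' and fills the truth block (planted coefficients, true mixture-intersection
#' CpG threshold, per-gene true class labels, noiseless signal).
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: list with `tf_raw`, `hm_raw`,
#'   `cpg_counts`, `truth` (list: `planted`, `threshold`, `label`,
#'   `component`, `noiseless`) and `config`.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_genes = 50, seed = 4))
#' dim(ds$tf_raw)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cp <- generate_cpg_counts(config)
  tf <- generate_tf_signals(config)
  hm <- generate_hm_response(tf, cp$label, config)
  mx <- config$cpg_mixture
  thr <- if (all(mx$sd > 0) && diff(range(mx$mean)) > 0) {
    tryCatch(mixture_threshold(mx$weight, mx$mean, mx$sd),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(tf_raw = tf, hm_raw = `attr<-`(hm, "noiseless", NULL),
                 cpg_counts = cp$counts,
                 truth = list(planted = config$planted, threshold = thr,
                              label = cp$label, component = cp$component,
                              noiseless = attr(hm, "noiseless")),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic promoter data set:", cfg$n_genes, "genes,", cfg$n_tfs,
      "TFs x", cfg$n_bins, "bins,", cfg$n_hms, "HMs\n")
  cat("  CpG classes (truth):", sum(x$truth$label == "poor"), "poor /",
      sum(x$truth$label == "rich"), "rich; true threshold",
      format(x$truth$threshold, digits = 4), "\n")
  invisible(x)
}

#' Noise level targeting a given signal-to-noise ratio
#'
#' Returns, per histone mark, the noise standard deviation for which the
#' planted linear signal explains approximately the fraction `r2` of the
#' response variance (`sd(signal) * sqrt((1 - r2) / r2)`), computed on a
#' noiseless realization of `config`.
#'
#' @param config A [synthetic_config()].
#' @param r2 Target fraction of explained variance.
#' @return Numeric vector, one noise sd per histone mark.
#' @export
noise_sd_for_r2 <- function(config, r2 = 0.8) {
  stopifnot(r2 > 0, r2 < 1)
  cfg0 <- config
  cfg0$noise_sd <- 0
  cp <- generate_cpg_counts(cfg0)
  tf <- generate_tf_signals(cfg0)
  hm <- generate_hm_response(tf, cp$label, cfg0)
  sds <- apply(attr(hm, "noiseless"), 2L, sd)
  sds * sqrt((1 - r2) / r2)
}
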