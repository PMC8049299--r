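#' Configuration of a full pipeline run
#'
#' Collects every knob of the end-to-end analysis: input mode, promoter
#' window geometry, penalty grids and fold counts, the significance levels of
#' the three inference stages, and the mandatory run seed.
#'
#' @param mode `"synthetic"` (generate data from `synthetic`), `"matrices"`
#'   (read TF/HM/CpG TSV files from `paths`), or `"extract"` (annotation +
#'   FASTA + per-track coverage via the promoter module).
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param paths Named list of input paths. Matrices mode: `tf`, `hm`, `cpg`
#'   (TSVs in the [write_matrix_tsv()] dialect; `cpg` has one column of
#'   counts). Extract mode: `annotation` (GTF/BED), `fasta` (genome FASTA),
#'   `tf_signals`, `hm_signals` (named vectors of coverage files readable by
#'   \pkg{rtracklayer}).
#' @param up,down,bin_width Promoter window geometry in bp (defaults
#'   500/500/100).
#' @param gamma_grid,outer_folds,inner_folds,n_lambda2,lambda2_min_ratio
#'   Penalty-selection parameters (see [cv_fused_lasso()]).
#' @param alpha_assoc F-test significance cutoff (default 0.005).
#' @param alpha_pc Bonferroni-corrected partial-correlation cutoff (default
#'   0.01).
#' @param n_perm Permutations per HM pair (default 10000).
#' @param alpha_perf BH-corrected Wilcoxon cutoff for the class performance
#'   comparison (default 0.05).
#' @param normalize_response Log-unit normalize the HM responses like the
#'   features (default `TRUE`).
#' @param cpg_bin_width CpG profile bin width in bp (extract mode).
#' @param seed Mandatory integer run seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "matrices", "extract"),
                            synthetic = synthetic_config(),
                            paths = list(),
                            up = 500, down = 500, bin_width = 100,
                            gamma_grid = default_gamma_grid(),
                            outer_folds = 5, inner_folds = 3,
                            n_lambda2 = 30, lambda2_min_ratio = 1e-5,
                            alpha_assoc = 0.005, alpha_pc = 0.01,
                            n_perm = 10000, alpha_perf = 0.05,
                            normalize_response = TRUE, cpg_bin_width = 5,
                            seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  alphas <- c(alpha_assoc, alpha_pc, alpha_perf)
  if (any(alphas <= 0) || any(alphas >= 1)) stop("alphas must be in (0, 1)")
  if ((up + down) %% bin_width != 0) {
    stop("window length must be divisible by 'bin_width'")
  }
  structure(list(mode = mode, synthetic = synthetic, paths = paths,
                 up = up, down = down, bin_width = bin_width,
                 n_bins = (up + down) %/% bin_width,
                 gamma_grid = gamma_grid, outer_folds = outer_folds,
                 inner_folds = inner_folds, n_lambda2 = n_lambda2,
                 lambda2_min_ratio = lambda2_min_ratio,
                 alpha_assoc = alpha_assoc, alpha_pc = alpha_pc,
                 n_perm = n_perm, alpha_perf = alpha_perf,
                 normalize_response = normalize_response,
                 cpg_bin_width = cpg_bin_width, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Compare outer-fold performance between the CpG classes for one mark
#'
#' Two-sample (unpaired) Wilcoxon rank-sum test on the outer-fold Pearson
#' correlations of the rich- vs poor-class models (the fold test sets contain
#' different genes in the two classes, so pairing is undefined); exact
#' small-sample p-value where possible. Benjamini-Hochberg correction across
#' marks is applied by the caller ([run_pipeline()]).
#'
#' @param fold_correlations_rich,fold_correlations_poor Numeric vectors of
#'   per-fold correlations (at least 3 folds each).
#' @param paired Use the signed-rank variant instead (requires equal length
#'   and a meaningful fold pairing; default `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
compare_performance <- function(fold_correlations_rich,
                                fold_correlations_poor, paired = FALSE) {
  if (length(fold_correlations_rich) < 3L ||
      length(fold_correlations_poor) < 3L) {
    stop("need at least 3 folds per class")
  }
  x <- fold_correlations_rich
  y <- fold_correlations_poor
  if (!paired && !any(outer(x, y, "=="))) {
    # exact Mann-Whitney p; ties within a group do not affect the rank sum,
    # so the exact null distribution still applies
    U <- sum(outer(x, y, ">"))
    n <- length(x); m <- length(y)
    p <- min(1, 2 * min(stats::pwilcox(U, n, m),
                        stats::pwilcox(U - 1, n, m, lower.tail = FALSE)))
    return(list(statistic = U, p_value = p))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# per-class normalized feature/response bundle
.normalize_class <- function(tf_raw, hm_raw, idx, normalize_response) {
  X <- normalize_log_unit(tf_raw[idx, , drop = FALSE])
  Y <- if (normalize_response) {
    normalize_log_unit(hm_raw[idx, , drop = FALSE])
  } else {
    hm_raw[idx, , drop = FALSE]
  }
  list(X = X, Y = Y, idx = idx)
}

.ingest <- function(config) {
  if (config$mode == "synthetic") {
    ds <- generate_dataset(config$synthetic)
    list(tf_raw = ds$tf_raw, hm_raw = ds$hm_raw, cpg = ds$cpg_counts,
         dataset = ds)
  } else if (config$mode == "matrices") {
    tf <- read_matrix_tsv(config$paths$tf)
    hm <- read_matrix_tsv(config$paths$hm)
    cpg <- read_matrix_tsv(config$paths$cpg)
    if (!identical(rownames(tf), rownames(hm)) ||
        !identical(rownames(tf), rownames(cpg))) {
      stop("gene order mismatch between TF, HM and CpG files")
    }
    list(tf_raw = tf, hm_raw = hm, cpg = drop(cpg[, 1L]), dataset = NULL)
  } else {
    .ingest_extract(config)
  }
}

.ingest_extract <- function(config) {
  for (pkg in c("rtracklayer", "Biostrings", "GenomicRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("extract mode requires the '", pkg, "' package")
    }
  }
  regions <- promoter_windows(config$paths$annotation, up = config$up,
                              down = config$down, n_bins = config$n_bins)
  genome <- Biostrings::readDNAStringSet(config$paths$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  keep <- !regions$excluded & regions$chrom %in% names(genome)
  regions <- structure(regions[keep, , drop = FALSE],
                       up = attr(regions, "up"), down = attr(regions, "down"),
                       n_bins = attr(regions, "n_bins"),
                       bin_width = attr(regions, "bin_width"),
                       class = class(regions))
  cpg <- vapply(seq_len(nrow(regions)), function(i) {
    s <- Biostrings::subseq(genome[[regions$chrom[i]]],
                            regions$start[i] + 1L, regions$end[i])
    count_cpg(as.character(s), bin_width = config$cpg_bin_width)$total
  }, numeric(1))
  names(cpg) <- regions$gene_id
  read_cov <- function(path) {
    gr <- rtracklayer::import(path)
    GenomicRanges::coverage(gr, weight = "score")
  }
  tf_cols <- lapply(config$paths$tf_signals, function(p) {
    extract_signal_matrix(read_cov(p), regions, statistic = "bin_means")
  })
  tf_raw <- do.call(cbind, tf_cols)
  colnames(tf_raw) <- paste0(rep(names(config$paths$tf_signals),
                                 each = config$n_bins),
                             ":", rep(seq_len(config$n_bins),
                                      length(tf_cols)))
  hm_cols <- lapply(config$paths$hm_signals, function(p) {
    extract_signal_matrix(read_cov(p), regions, statistic = "window_mean")
  })
  hm_raw <- do.call(cbind, hm_cols)
  colnames(hm_raw) <- names(config$paths$hm_signals)
  list(tf_raw = tf_raw, hm_raw = hm_raw, cpg = cpg, dataset = NULL,
       regions = regions)
}

#' Run the full CpG-stratified association pipeline
#'
#' Executes the study end to end: data ingest or synthesis, CpG partition of
#' the promoters, per-class log-unit normalization, one nested
#' cross-validated fused-LASSO model per (histone mark, class) for classes
#' poor / rich / all, F-test association tables, partial correlations
#' between marks per class, and the Wilcoxon/BH performance comparison
#' between the two class models. All numeric artifacts are written as TSV/
#' JSON with fixed 12-significant-digit formatting, so rerunning an identical
#' config reproduces them byte-exactly; a plain-text `run.log` records gene
#' counts, selected penalties and wall-clock checkpoints.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `partition`, `models` (per mark and class:
#'   the [cv_fused_lasso] objects), `associations` (ranked tables),
#'   `sign_matrix`, `pc` (per class), `comparison` (data frame) and `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  logmsg <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", sprintf(...), "\n",
        file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED: %s", name, conditionMessage(e))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
    logmsg("stage %s: done", name)
    res
  }

  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)

  dat <- stage("ingest", .ingest(config))
  logmsg("ingest: %d genes, %d TF features, %d HMs", nrow(dat$tf_raw),
         ncol(dat$tf_raw), ncol(dat$hm_raw))
  if (config$mode == "synthetic") {
    write_matrix_tsv(dat$tf_raw, file.path(outdir, "tf_raw.tsv"))
    write_matrix_tsv(dat$hm_raw, file.path(outdir, "hm_raw.tsv"))
    cpgm <- matrix(dat$cpg, ncol = 1,
                   dimnames = list(rownames(dat$tf_raw), "cpg_count"))
    write_matrix_tsv(cpgm, file.path(outdir, "cpg_counts.tsv"))
    .write_truth_sidecar(config$synthetic,
                         file.path(outdir, "truth_planted.tsv"))
  }

  part <- stage("cpg_split",
                fit_bimodal_split(dat$cpg, seed = config$seed))
  logmsg("split: threshold %.4f, %d poor / %d rich", part$threshold,
         sum(part$labels == "poor"), sum(part$labels == "rich"))
  .write_tsv_df(data.frame(gene_id = rownames(dat$tf_raw),
                           cpg_count = dat$cpg,
                           class = as.character(part$labels)),
                file.path(outdir, "cpg_partition.tsv"))

  n <- nrow(dat$tf_raw)
  class_idx <- list(poor = which(part$labels == "poor"),
                    rich = which(part$labels == "rich"),
                    all = seq_len(n))
  hm_names <- colnames(dat$hm_raw)
  k <- if (config$mode == "synthetic") config$synthetic$n_bins else
    config$n_bins

  models <- list()
  assoc <- list()
  norm <- lapply(class_idx, function(idx) {
    .normalize_class(dat$tf_raw, dat$hm_raw, idx, config$normalize_response)
  })

  mcount <- 0L
  for (h in seq_along(hm_names)) {
    for (ci in seq_along(class_idx)) {
      cl <- names(class_idx)[ci]
      mid <- paste0(hm_names[h], "_", cl)
      mcount <- mcount + 1L
      bun <- norm[[ci]]
      cv <- stage(paste0("fit_", mid),
                  cv_fused_lasso(bun$X, bun$Y[, h], n_bins = k,
                                 gamma_grid = config$gamma_grid,
                                 outer_folds = config$outer_folds,
                                 inner_folds = config$inner_folds,
                                 n_lambda2 = config$n_lambda2,
                                 lambda2_min_ratio = config$lambda2_min_ratio,
                                 seed = config$seed + 100L * mcount))
      logmsg("fit %s: gamma %.4g lambda2 %.4g mean pearson %.3f", mid,
             cv$selected$gamma, cv$selected$lambda2, mean(cv$folds$pearson))
      models[[mid]] <- cv
      .write_tsv_df(cv$folds, file.path(outdir, paste0("cv_", mid, ".tsv")))
      .write_fit_json(cv$final_fit, file.path(outdir,
                                              paste0("fit_", mid, ".json")))
      at <- stage(paste0("associate_", mid), {
        full <- tf_association(cv$final_fit, bun$X, bun$Y[, h])
        rank_associations(full, alpha = config$alpha_assoc)
      })
      assoc[[mid]] <- at
      .write_tsv_df(as.data.frame(at),
                    file.path(outdir, paste0("assoc_", mid, ".tsv")))
    }
  }

  sign_mat <- association_sign_matrix(assoc)
  .write_named_matrix(sign_mat, file.path(outdir, "assoc_sign_matrix.tsv"),
                      id_name = "tf")

  pc <- stage("pcor", {
    lab <- part$labels
    res <- list()
    for (ci in 1:2) {
      cl <- c("poor", "rich")[ci]
      bun <- norm[[cl]]
      res[[cl]] <- .pc_one_class(bun$Y, cl, config$alpha_pc, config$n_perm,
                                 config$seed + 5000L, ci, "two.sided", TRUE)
    }
    res
  })
  for (cl in names(pc)) {
    r <- pc[[cl]]
    .write_named_matrix(r$rho, file.path(outdir, paste0("pcor_", cl, "_rho.tsv")),
                        id_name = "hm")
    .write_named_matrix(r$p_bonf,
                        file.path(outdir, paste0("pcor_", cl, "_p_bonf.tsv")),
                        id_name = "hm")
  }
  .write_tsv_df(.pc_long(pc), file.path(outdir, "pcor_long.tsv"))

  comparison <- stage("compare", {
    rows <- lapply(hm_names, function(h) {
      rich <- models[[paste0(h, "_rich")]]$folds$pearson
      poor <- models[[paste0(h, "_poor")]]$folds$pearson
      alln <- models[[paste0(h, "_all")]]$folds$pearson
      cp <- compare_performance(rich, poor)
      data.frame(hm = h, mean_pearson_rich = mean(rich),
                 mean_pearson_poor = mean(poor),
                 mean_pearson_all = mean(alln),
                 wilcoxon_W = cp$statistic, p_value = cp$p_value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < config$alpha_perf
    out
  })
  .write_tsv_df(comparison, file.path(outdir, "performance_comparison.tsv"))
  logmsg("pipeline complete")

  invisible(list(partition = part, models = models, associations = assoc,
                 sign_matrix = sign_mat, pc = pc, comparison = comparison,
                 outdir = outdir, config = config))
}

.pc_long <- function(pc) {
  rows <- list()
  for (cl in names(pc)) {
    r <- pc[[cl]]
    pr <- utils::combn(length(r$hm_names), 2L)
    for (q in seq_len(ncol(pr))) {
      i <- pr[1L, q]; j <- pr[2L, q]
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, hm1 = r$hm_names[i], hm2 = r$hm_names[j],
        rho = r$rho[i, j], p_raw = r$p_raw[i, j], p_bonf = r$p_bonf[i, j],
        significant = r$significant[i, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(lambda1 = fit$lambda1, lambda2 = fit$lambda2, gamma = fit$gamma,
         beta0 = fit$beta0, coefficients = as.list(fit$beta),
         blocks = fit$blocks, df = fit$df, rss = fit$rss,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_truth_sidecar <- function(scfg, path) {
  rows <- list()
  if (!is.null(scfg$planted)) {
    for (hm in names(scfg$planted)) {
      for (cl in names(scfg$planted[[hm]])) {
        map <- scfg$planted[[hm]][[cl]]
        for (nm in names(map)) {
          rows[[length(rows) + 1L]] <- data.frame(
            hm = hm, class = cl, tf_index = as.integer(nm),
            bin = seq_along(map[[nm]]), coefficient = map[[nm]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hm = character(0), class = character(0),
               tf_index = integer(0), bin = integer(0),
               coefficient = numeric(0))
  .write_tsv_df(df, path)
}
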