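test_that("promoter windows are strand-aware, clipped and validated", {
  anno <- data.frame(gene_id = c("gp", "gm", "gc"),
                     chrom = "chr1",
                     tss = c(10000, 10000, 300),
                     strand = c("+", "-", "+"))
  reg <- promoter_windows(anno, up = 500, down = 500, n_bins = 10)
  expect_equal(reg$start[1], 9500)
  expect_equal(reg$end[1], 10500)
  expect_equal(reg$start[2], 9500) # symmetric window, minus strand
  expect_equal(reg$end[2], 10500)
  expect_true(reg$excluded[3]) # would start at -200
  expect_false(any(reg$excluded[1:2]))
  ed <- bin_edges(reg)
  expect_equal(ed[1, 1:2], c(9500, 9600)) # plus-strand bin 1 = [9500, 9600)

  expect_error(promoter_windows(anno[c(1, 1), ]), "duplicate gene ids")
  anno$strand[2] <- "*"
  expect_error(promoter_windows(anno), "strand")
  expect_error(promoter_windows(anno[1, ], up = 500, down = 500, n_bins = 7),
               "divisible")
})

test_that("binning averages per bin and reverses on the minus strand", {
  expect_equal(bin_signal(rep(2, 1000), 10), rep(2, 10))
  cov <- c(rep(1, 100), rep(0, 900))
  expect_equal(bin_signal(cov, 10, "+"), c(1, rep(0, 9)))
  # independent oracle: explicit coordinate reversal
  expect_equal(bin_signal(cov, 10, "-"), bin_signal(rev(cov), 10, "+"))
  expect_equal(bin_signal(cov, 10, "-"), c(rep(0, 9), 1))
  expect_error(bin_signal(rep(1, 995), 10), "multiple")
})

test_that("window mean equals the mean of bin means (tiling conservation)", {
  expect_equal(aggregate_response(rep(3.5, 1000)), 3.5)
  expect_equal(aggregate_response(c(rep(0, 500), rep(1, 500))), 0.5)
  set.seed(4)
  for (i in 1:5) {
    cov <- rexp(1000)
    expect_equal(aggregate_response(cov), mean(bin_signal(cov, 10)),
                 tolerance = 1e-12)
  }
  expect_error(aggregate_response(rep(1, 10), window_length = 1000),
               "length")
})

test_that("log-unit normalization maps to [0,1] and round-trips", {
  expect_equal(normalize_log_unit(c(0, 9, 99), pseudocount = 1),
               c(0, 0.5, 1))
  expect_equal(normalize_log_unit(rep(7, 5)), rep(0, 5))
  expect_error(normalize_log_unit(c(-1, 2)), "nonnegative")
  set.seed(8)
  M <- matrix(rexp(200, 0.1), 50, 4)
  N <- normalize_log_unit(M)
  expect_true(all(N >= 0 & N <= 1))
  expect_equal(unname(apply(N, 2, min)), rep(0, 4))
  expect_equal(unname(apply(N, 2, max)), rep(1, 4))
  # invert through exp/shift and renormalize: identity within 1e-9
  l <- log(M[, 1] + 1)
  recon <- exp(N[, 1] * (max(l) - min(l)) + min(l)) - 1
  expect_equal(normalize_log_unit(recon), N[, 1], tolerance = 1e-9)
})

test_that("CpG counting scans CG dinucleotides into profile bins", {
  expect_equal(count_cpg("CGCGCG", bin_width = 6)$total, 3)
  expect_equal(count_cpg("ATATAT", bin_width = 6)$total, 0)
  r <- count_cpg("ACGTACGT", bin_width = 4)
  expect_equal(r$total, 2)
  expect_equal(r$profile, c(1, 1))
  # boundary-straddling CG goes to the bin of its C
  r2 <- count_cpg("AAACGAAA", bin_width = 4)
  expect_equal(r2$profile, c(1, 0))
  expect_error(count_cpg("ACGTA", bin_width = 4), "multiple")
  expect_error(count_cpg("ACGX", bin_width = 4), "A, C, G, T, N")
})

test_that("bimodal split recovers mixture parameters and the midpoint", {
  set.seed(31)
  x <- c(rnorm(5000, 20, 3), rnorm(5000, 60, 3))
  p <- fit_bimodal_split(x, seed = 1)
  # symmetric equal-sd mixture: threshold is the midpoint
  expect_lt(abs(p$threshold - 40), 1)
  # EM mean recovery within 3 standard errors at n = 1e4
  expect_lt(abs(p$mean[1] - 20), 3 * 3 / sqrt(5000))
  expect_lt(abs(p$mean[2] - 60), 3 * 3 / sqrt(5000))
  expect_gt(p$threshold, p$mean[1])
  expect_lt(p$threshold, p$mean[2])
  # every gene gets exactly one label, split at the threshold
  expect_identical(sum(p$labels == "poor") + sum(p$labels == "rich"),
                   length(x))
  expect_identical(p$labels == "poor", x < p$threshold)
  expect_error(fit_bimodal_split(rep(5, 100)), "distinct")
})

test_that("EM agrees with an independent mixture fitter (mclust)", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust") # Mclust needs its helpers on the search path
  set.seed(33)
  x <- c(rnorm(700, 15, 2), rnorm(1300, 50, 6))
  p <- fit_bimodal_split(x, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mc_means <- sort(mc$parameters$mean)
  expect_lt(max(abs(p$mean - mc_means)), 0.5)
  expect_lt(max(abs(sort(p$weight) - sort(mc$parameters$pro))), 0.05)
})

test_that("signal extraction honours regions, strand and missing chromosomes", {
  anno <- data.frame(gene_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chrZ"),
                     tss = c(600, 700, 600), strand = c("+", "-", "+"))
  reg <- promoter_windows(anno, up = 500, down = 500, n_bins = 10)
  cov <- list(chr1 = c(rep(0, 200), rep(2, 100), rep(0, 1100)))
  expect_warning(M <- extract_signal_matrix(cov, reg), "absent")
  expect_identical(rownames(M), c("a", "b"))
  # gene a window [100,1100): signal occupies its second bin
  expect_equal(M["a", ], c(0, 2, rep(0, 8)))
  # gene b is minus strand, window [200,1200): signal is genomically leftmost
  # = most downstream in gene orientation
  expect_equal(M["b", ], c(rep(0, 9), 2))
  expect_warning(wm <- extract_signal_matrix(cov, reg,
                                             statistic = "window_mean"),
                 "absent")
  expect_equal(unname(wm["a"]), 0.2)
})

test_that("coverage files reach binned matrices through the extract path", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t600\t900\tgA\t0\t+",
               "chr1\t100\t800\tgB\t0\t-"), bed)
  reg <- promoter_windows(bed, up = 500, down = 500, n_bins = 10)
  # BED is already 0-based: gA TSS 600 (+), gB TSS 799 (-)
  expect_equal(reg$tss[reg$gene_id == "gA"], 600)
  expect_equal(reg$tss[reg$gene_id == "gB"], 799)

  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t200\t0",
               "chr1\t200\t300\t3",
               "chr1\t300\t1500\t0"), bg)
  cov <- GenomicRanges::coverage(rtracklayer::import(bg), weight = "score")
  M <- extract_signal_matrix(cov, reg)
  # gA window [100,1100): the 3-signal fills bin 2 in gene orientation
  expect_equal(M["gA", ], c(0, 3, rep(0, 8)))
  # gB (minus) window [299,1299): one bp of signal lands in the last
  # genomic bin counted from the right, i.e. gene-orientation bin 10
  expect_equal(unname(M["gB", 10]), 3 * 1 / 100)
})

test_that("GTF annotation yields most-5' protein-coding TSSs in 0-based coords", {
  skip_if_not_installed("rtracklayer")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\t",
           'gene_id "gA"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\ttranscript\t1201\t2000\t.\t+\t.\t",
           'gene_id "gA"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\ttranscript\t3001\t4000\t.\t-\t.\t",
           'gene_id "gB"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\ttranscript\t3001\t3600\t.\t-\t.\t",
           'gene_id "gB"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\ttranscript\t5001\t6000\t.\t+\t.\t",
           'gene_id "gC"; gene_biotype "lincRNA";')
  ), gtf)
  reg <- promoter_windows(gtf, up = 500, down = 500, n_bins = 10)
  expect_setequal(reg$gene_id, c("gA", "gB"))
  # gA: most 5' TSS is 1-based 1001 -> 0-based 1000
  expect_equal(reg$tss[reg$gene_id == "gA"], 1000)
  # gB (minus): most 5' TSS is the larger end 4000 -> 0-based 3999
  expect_equal(reg$tss[reg$gene_id == "gB"], 3999)
})
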