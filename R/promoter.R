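#' Strand-aware promoter windows around the TSS
#'
#' Defines, for each gene, a promoter window from `up` bp upstream to `down`
#' bp downstream of the TSS (0-based, half-open, BED convention) together
#' with `n_bins` equal-width bins. Bins are indexed upstream-to-downstream in
#' *gene* orientation: for minus-strand genes bin 1 is the genomically
#' rightmost bin, so "bin 1" means the same promoter position for every gene.
#' Windows that would extend below coordinate 0 are flagged for exclusion.
#'
#' @param annotation One of: a data frame with columns `gene_id`, `chrom`,
#'   `tss` (0-based TSS coordinate) and `strand` (`+`/`-`); a `GRanges` of
#'   gene or transcript ranges with a `gene_id` (or `name`) metadata column;
#'   or a path to a GTF or BED file (read via \pkg{rtracklayer}; GTF 1-based
#'   coordinates are converted on read, and when a gene has several
#'   transcripts its most 5' TSS in gene orientation is used; rows annotated
#'   with a biotype keep only `protein_coding`).
#' @param up,down Window extent in bp upstream/downstream of the TSS
#'   (defaults 500/500). `up + down` must be divisible by `n_bins`.
#' @param n_bins Number of bins (default 10, i.e. 100-bp bins).
#' @return Data frame of class `promoter_regions` with columns `gene_id`,
#'   `chrom`, `tss`, `strand`, `start`, `end` (half-open genomic window) and
#'   `excluded`; attributes `up`, `down`, `n_bins`, `bin_width`.
#' @examples
#' promoter_windows(data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
#'                             strand = "+"))
#' @export
promoter_windows <- function(annotation, up = 500, down = 500, n_bins = 10) {
  if ((up + down) %% n_bins != 0) {
    stop("window length (up + down) must be divisible by 'n_bins'")
  }
  anno <- .as_tss_table(annotation)
  if (anyDuplicated(anno$gene_id)) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(anno$gene_id[duplicated(anno$gene_id)]), collapse = ", "))
  }
  if (any(is.na(anno$strand)) || !all(anno$strand %in% c("+", "-"))) {
    stop("every gene needs a '+' or '-' strand")
  }
  start <- ifelse(anno$strand == "+", anno$tss - up, anno$tss - down)
  end <- start + up + down
  excluded <- start < 0
  out <- data.frame(gene_id = anno$gene_id, chrom = anno$chrom,
                    tss = anno$tss, strand = anno$strand,
                    start = pmax(start, 0), end = end, excluded = excluded,
                    stringsAsFactors = FALSE)
  structure(out, up = up, down = down, n_bins = as.integer(n_bins),
            bin_width = (up + down) %/% n_bins,
            class = c("promoter_regions", "data.frame"))
}

.as_tss_table <- function(annotation) {
  if (is.data.frame(annotation)) {
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(annotation))) {
      stop("annotation data frame needs columns: ", paste(need, collapse = ", "))
    }
    return(annotation[need])
  }
  if (inherits(annotation, "GRanges")) return(.granges_tss(annotation))
  if (is.character(annotation) && length(annotation) == 1L) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading annotation files requires the 'rtracklayer' package")
    }
    gr <- rtracklayer::import(annotation)
    return(.granges_tss(gr))
  }
  stop("unsupported annotation input")
}

# Most 5' TSS per gene in gene orientation; GRanges is 1-based, convert to
# 0-based: plus-strand TSS = start - 1, minus-strand TSS = end - 1.
.granges_tss <- function(gr) {
  mc <- as.data.frame(gr)
  type_col <- intersect(c("gene_biotype", "gene_type", "transcript_biotype"),
                        names(mc))
  if (length(type_col)) {
    keep <- mc[[type_col[1L]]] %in% "protein_coding" | is.na(mc[[type_col[1L]]])
    mc <- mc[keep, , drop = FALSE]
  }
  if ("type" %in% names(mc) && any(mc$type %in% c("transcript", "mRNA"))) {
    mc <- mc[mc$type %in% c("transcript", "mRNA"), , drop = FALSE]
  }
  id_col <- intersect(c("gene_id", "name", "gene_name"), names(mc))
  if (!length(id_col)) stop("annotation lacks a gene_id/name column")
  ids <- as.character(mc[[id_col[1L]]])
  strand <- as.character(mc$strand)
  tss <- ifelse(strand == "+", mc$start - 1L, mc$end - 1L)
  # most 5' in gene orientation: min tss on +, max tss on -
  ord <- order(ids, ifelse(strand == "+", tss, -tss))
  first <- !duplicated(ids[ord])
  sel <- ord[first]
  data.frame(gene_id = ids[sel], chrom = as.character(mc$seqnames)[sel],
             tss = tss[sel], strand = strand[sel], stringsAsFactors = FALSE)
}

#' Genomic bin edges of promoter windows
#'
#' @param regions A [promoter_windows()] result.
#' @return Integer matrix (genes x `n_bins + 1`) of genomic bin boundary
#'   coordinates (always left-to-right in genome orientation).
#' @export
bin_edges <- function(regions) {
  stopifnot(inherits(regions, "promoter_regions"))
  k <- attr(regions, "n_bins")
  w <- attr(regions, "bin_width")
  t(vapply(regions$start, function(s) s + (0:k) * w, numeric(k + 1)))
}

#' Average per-bp coverage inside promoter bins
#'
#' Splits a per-bp coverage vector (genome orientation, left to right) into
#' `n_bins` equal-width bins and returns the arithmetic mean per bin, in
#' *gene* orientation (the bin order is reversed for minus-strand genes).
#'
#' @param coverage Numeric per-bp coverage over the window.
#' @param n_bins Number of bins; `length(coverage)` must be a multiple.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of `n_bins` bin means, bin 1 most upstream in gene
#'   orientation.
#' @export
bin_signal <- function(coverage, n_bins = 10, strand = "+") {
  if (!is.numeric(coverage) || length(coverage) %% n_bins != 0L) {
    stop("coverage length must be a multiple of 'n_bins'")
  }
  strand <- match.arg(strand, c("+", "-"))
  mns <- colMeans(matrix(coverage, ncol = n_bins))
  if (strand == "-") rev(mns) else mns
}

#' Window-mean response signal
#'
#' Arithmetic mean of per-bp coverage over the whole promoter window (the
#' response value for one histone mark at one gene). When the bins tile the
#' window this equals the mean of the bin means.
#'
#' @param coverage Numeric per-bp coverage over the window.
#' @param window_length Optional expected length; mismatch is an error.
#' @return Scalar mean coverage.
#' @export
aggregate_response <- function(coverage, window_length = NULL) {
  if (!is.numeric(coverage) || !length(coverage)) {
    stop("coverage must be a non-empty numeric vector")
  }
  if (!is.null(window_length) && length(coverage) != window_length) {
    stop("coverage length does not match the window length")
  }
  mean(coverage)
}

#' Log-unit normalization of nonnegative signals
#'
#' Maps each column `x` to `(log(x + pseudocount) - min) / (max - min)`, the
#' feature space of the regression model: values in `[0, 1]`, robust to
#' right-skewed raw counts and differing signal strength. Constant columns
#' (no information) map to all zeros.
#'
#' @param x Nonnegative numeric vector or matrix (columns normalized
#'   independently).
#' @param pseudocount Positive value added before the log (guards `log(0)`).
#' @return Object of the same shape with entries in `[0, 1]`.
#' @examples
#' normalize_log_unit(c(0, 9, 99), pseudocount = 1) # 0, 0.5, 1
#' @export
normalize_log_unit <- function(x, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(x < 0)) stop("signals must be nonnegative")
  norm1 <- function(v) {
    l <- log(v + pseudocount)
    r <- max(l) - min(l)
    if (r == 0) rep(0, length(v)) else (l - min(l)) / r
  }
  if (is.matrix(x)) {
    out <- apply(x, 2L, norm1)
    dimnames(out) <- dimnames(x)
    out
  } else {
    norm1(x)
  }
}

#' Count CpG dinucleotides in a promoter window
#'
#' Counts `CG` dinucleotide occurrences in the window sequence, plus a
#' positional profile in consecutive bins of `bin_width` bp; a CG straddling
#' a profile-bin boundary is assigned to the bin of its C.
#'
#' @param sequence Character DNA string over `A,C,G,T,N` (or any object with
#'   an `as.character` method, e.g. a `Biostrings::DNAString`), of the window
#'   length.
#' @param bin_width Profile bin width in bp (default 5); must divide the
#'   sequence length.
#' @return List with `total` (CG count) and `profile` (integer counts per
#'   bin).
#' @examples
#' count_cpg("ACGTACGT", bin_width = 4) # total 2, profile c(1, 1)
#' @export
count_cpg <- function(sequence, bin_width = 5) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence must contain only A, C, G, T, N")
  }
  n <- nchar(sequence)
  if (n %% bin_width != 0L) {
    stop("sequence length must be a multiple of 'bin_width'")
  }
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  pos <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  nb <- n %/% bin_width
  profile <- tabulate((pos - 1L) %/% bin_width + 1L, nbins = nb)
  list(total = length(pos), profile = profile)
}

#' Extract binned or window-mean signal for promoter regions
#'
#' Pulls per-bp coverage for each (non-excluded) promoter window from a
#' per-chromosome coverage object and reduces it with [bin_signal()]
#' (features) or [aggregate_response()] (responses). Coverage is a named list
#' of numeric vectors, or an `RleList` such as
#' `rtracklayer::import(bigwig, as = "RleList")` returns. Regions on
#' chromosomes absent from the coverage (unassayed) are dropped with a
#' warning.
#'
#' @param coverage Named per-chromosome coverage (numeric vectors or an
#'   `RleList`).
#' @param regions A [promoter_windows()] result.
#' @param statistic `"bin_means"` (genes x `n_bins` matrix, gene orientation)
#'   or `"window_mean"` (named vector).
#' @return Matrix or vector with gene ids as row/element names.
#' @export
extract_signal_matrix <- function(coverage, regions,
                                  statistic = c("bin_means", "window_mean")) {
  stopifnot(inherits(regions, "promoter_regions"))
  statistic <- match.arg(statistic)
  k <- attr(regions, "n_bins")
  keep <- !regions$excluded
  miss <- !(regions$chrom %in% names(coverage))
  if (any(miss & keep)) {
    warning("dropping ", sum(miss & keep),
            " region(s) on chromosomes absent from the coverage")
    keep <- keep & !miss
  }
  rows <- which(keep)
  get_cov <- function(chrom, from, to) {
    v <- coverage[[chrom]]
    if (to > length(v)) stop("window beyond end of coverage for ", chrom)
    as.numeric(v[(from + 1L):to]) # 0-based half-open -> 1-based inclusive
  }
  if (statistic == "bin_means") {
    out <- matrix(NA_real_, length(rows), k,
                  dimnames = list(regions$gene_id[rows], NULL))
    for (i in seq_along(rows)) {
      r <- rows[i]
      cv <- get_cov(regions$chrom[r], regions$start[r], regions$end[r])
      out[i, ] <- bin_signal(cv, n_bins = k, strand = regions$strand[r])
    }
    out
  } else {
    out <- vapply(rows, function(r) {
      aggregate_response(get_cov(regions$chrom[r], regions$start[r],
                                 regions$end[r]))
    }, numeric(1))
    names(out) <- regions$gene_id[rows]
    out
  }
}
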