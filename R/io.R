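# 12 significant digits everywhere so reruns are byte-identical
.fmt <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

#' Write a signal matrix in the pipeline TSV dialect
#'
#' UTF-8, tab-separated, first column `gene_id`, remaining columns the matrix
#' columns (TF files use `tf_name:bin_index` headers, HM files the mark
#' name). Signal matrices are serialized with 17 significant digits so a
#' write/read round trip reproduces the doubles bit-exactly (derived report
#' tables use 12 digits); either way identical runs produce byte-identical
#' files.
#'
#' @param mat Numeric matrix with gene rownames and column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix needs gene rownames and column names")
  }
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a signal matrix in the pipeline TSV dialect
#'
#' Strict parser for the dialect written by [write_matrix_tsv()]: ragged
#' rows, non-numeric cells and duplicate gene ids are errors naming the
#' offending row.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("no data rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  p <- length(header) - 1L
  if (p < 1L) stop("header must list gene_id plus at least one column")
  ids <- character(length(lines) - 1L)
  out <- matrix(NA_real_, length(lines) - 1L, p)
  for (i in 2:length(lines)) {
    row <- parts[[i]]
    if (length(row) != p + 1L) {
      stop("ragged row ", i, " in ", path, ": expected ", p + 1L,
           " fields, got ", length(row))
    }
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      stop("non-numeric value in row ", i, " of ", path)
    }
    ids[i - 1L] <- row[1L]
    out[i - 1L, ] <- vals
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dimnames(out) <- list(ids, header[-1L])
  out
}

# generic data-frame writer using the same numeric formatting
.write_tsv_df <- function(df, path) {
  header <- paste(names(df), collapse = "\t")
  cols <- lapply(df, .fmt)
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

.write_named_matrix <- function(mat, path, id_name = "id") {
  header <- paste(c(id_name, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
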