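#' Expression and count matrices
#'
#' Expression values are stored as plain numeric matrices with genes in rows
#' and samples in columns; `rownames()` are gene ids and `colnames()` sample
#' ids. TPM matrices hold non-negative reals in transcripts-per-million
#' units; count matrices hold RSEM-style expected counts, which may be
#' non-integer (they are rounded only inside the exact test).
#'
#' `validate_expression_matrix()` checks the invariants shared by both:
#' non-negative values, unique gene and sample ids, consistent dimensions.
#'
#' @param m numeric matrix, genes x samples, with row and column names.
#' @param what label used in error messages.
#' @return `m`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("%s must have gene rownames and sample colnames", what))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("duplicate gene ids in %s", what))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("duplicate sample ids in %s", what))
  }
  if (anyNA(m)) abort(sprintf("missing values in %s", what))
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative value in %s at gene '%s', sample '%s'",
      what, rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  invisible(m)
}

#' Read a gene-by-sample expression matrix
#'
#' Two on-disk layouts are supported. `"tsv"` is a tab-separated table with
#' a header row of sample ids and gene ids in the first column. `"mtx"` is
#' MatrixMarket coordinate format with two plain-text sidecar files, one id
#' per line: `<path>.rownames` (genes) and `<path>.colnames` (samples).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) {
        abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
      }
    )
    if (ncol(df) < 2) abort(sprintf("no sample columns in %s", path))
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(apply(vals, 2, as.numeric))),
                   arr.ind = TRUE)
      abort(sprintf(
        "non-numeric entry in %s near data line %d", path,
        if (length(bad)) bad[1] else 1L
      ))
    }
    rownames(vals) <- as.character(df[[1]])
    m <- vals
  } else {
    sp <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".rownames"))
    samples <- readLines(paste0(path, ".colnames"))
    if (nrow(sp) != length(genes) || ncol(sp) != length(samples)) {
      abort(sprintf(
        "sidecar name files do not match matrix dimensions for %s", path
      ))
    }
    m <- as.matrix(sp)
    dimnames(m) <- list(genes, samples)
  }
  validate_expression_matrix(m, sprintf("matrix read from %s", path))
  m
}

#' Write a gene-by-sample expression matrix
#'
#' Inverse of [read_expression_matrix()]; the `"mtx"` writer emits the
#' coordinate file plus `.rownames`/`.colnames` sidecars.
#'
#' @inheritParams read_expression_matrix
#' @param m matrix to write.
#' @param gene_col name of the gene-id column in the TSV layout.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, format = c("tsv", "mtx"),
                                    gene_col = "gene_id") {
  format <- match.arg(format)
  validate_expression_matrix(m)
  if (format == "tsv") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- gene_col
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' log2(x + 1) transform
#'
#' The standard working scale for TPM: zeros stay zero and the transform is
#' monotone on `[0, Inf)`.
#'
#' @param m non-negative numeric matrix (or vector).
#' @return object of the same shape on the log2(TPM+1) scale.
#' @export
log2p1 <- function(m) {
  if (any(m < 0, na.rm = TRUE)) abort("log2p1() requires non-negative input")
  log2(m + 1)
}

#' Call gene detection at a TPM threshold
#'
#' A gene is detected in a sample when its TPM is strictly greater than
#' `threshold` (default 1 TPM; the boundary value itself is not detected).
#' The threshold is recorded as an attribute so downstream summaries can
#' report the rule used.
#'
#' @param m TPM matrix.
#' @param threshold detection cutoff in TPM units, `>= 0`.
#' @return logical matrix of the same shape with attribute `"threshold"`.
#' @export
detection_matrix <- function(m, threshold = 1) {
  validate_expression_matrix(m)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  d <- m > threshold
  attr(d, "threshold") <- threshold
  d
}

#' Per-sample detected-gene counts
#'
#' @inheritParams detection_matrix
#' @return tibble with `sample_id` and `genes_detected`.
#' @export
detected_genes <- function(m, threshold = 1) {
  d <- detection_matrix(m, threshold)
  tibble(sample_id = colnames(m), genes_detected = colSums(d))
}

#' Construct a sample metadata table
#'
#' @param sample_id character vector, unique.
#' @param condition experimental condition per sample
#'   (`"HC"`, `"NE"`, `"saline"`, `"PTZ"`).
#' @param stain FOS immunostain label per sample
#'   (`"FOS_POS"`, `"FOS_NEG"`, `"UNKNOWN"`).
#' @param mapped_reads uniquely mapped read count per sample.
#' @return tibble with one row per sample and a `qc_pass` column
#'   initialised to `NA` (set by [apply_qc()]).
#' @export
sample_metadata <- function(sample_id, condition = "NE", stain = "UNKNOWN",
                            mapped_reads = NA_real_) {
  if (anyDuplicated(sample_id)) abort("sample_id values must be unique")
  condition <- match_levels(condition, c("HC", "NE", "saline", "PTZ"),
                            length(sample_id), "condition")
  stain <- match_levels(stain, c("FOS_POS", "FOS_NEG", "UNKNOWN"),
                        length(sample_id), "stain")
  if (any(!is.na(mapped_reads) & mapped_reads < 0)) {
    abort("mapped_reads must be non-negative")
  }
  tibble(
    sample_id = as.character(sample_id),
    condition = condition,
    stain = stain,
    mapped_reads = rep_len(as.numeric(mapped_reads), length(sample_id)),
    qc_pass = NA
  )
}

match_levels <- function(x, levels, n, what) {
  x <- rep_len(as.character(x), n)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    abort(sprintf("invalid %s value(s): %s", what,
                  paste(bad, collapse = ", ")))
  }
  x
}
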