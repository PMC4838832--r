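#' Sample-level quality control
#'
#' Three exclusion criteria are applied to every nucleus:
#' (i) more than `min_reads` uniquely mapped reads (strictly greater,
#' default 50,000); (ii) ERCC spike-in TPM significantly positively
#' correlated with expected input concentration at `alpha`; (iii) a
#' detected-gene count no lower than the batch mean minus two standard
#' deviations.
#'
#' @name qc
NULL

#' Mapped-read criterion
#'
#' @param mapped_reads numeric vector of uniquely mapped read counts.
#' @param min_reads threshold; a sample passes iff strictly greater.
#' @return logical vector.
#' @export
qc_reads <- function(mapped_reads, min_reads = 50000) {
  if (any(mapped_reads < 0, na.rm = TRUE)) {
    abort("mapped_reads must be non-negative")
  }
  !is.na(mapped_reads) & mapped_reads > min_reads
}

#' ERCC spike-in correlation criterion
#'
#' Pearson correlation of log2(observed TPM + 1) against log2(expected
#' concentration), tested one-sided for positive association via the t
#' transform with n - 2 degrees of freedom. A sample passes iff p <
#' `alpha` and r > 0. Fewer than 3 spikes with nonzero observed TPM, or
#' zero variance on either axis, is an automatic fail with the reason
#' recorded.
#'
#' @param observed_tpm per-spike observed TPM vector.
#' @param expected per-spike expected concentration vector, aligned.
#' @param alpha significance level.
#' @return one-row tibble: `ercc_r`, `ercc_p`, `ercc_pass`, `reason`.
#' @export
qc_ercc_correlation <- function(observed_tpm, expected, alpha = 0.05) {
  if (length(observed_tpm) != length(expected)) {
    abort("observed and expected spike vectors must be aligned")
  }
  fail <- function(reason) {
    tibble(ercc_r = NA_real_, ercc_p = NA_real_, ercc_pass = FALSE,
           reason = reason)
  }
  if (sum(observed_tpm > 0) < 3) return(fail("fewer than 3 nonzero spikes"))
  x <- log2(observed_tpm + 1)
  y <- log2(expected)
  if (sd(x) == 0 || sd(y) == 0) return(fail("zero variance"))
  ct <- cor.test(x, y, alternative = "greater", method = "pearson")
  tibble(ercc_r = unname(ct$estimate), ercc_p = ct$p.value,
         ercc_pass = ct$p.value < alpha && ct$estimate > 0,
         reason = NA_character_)
}

#' Detected-gene-count criterion
#'
#' The threshold is the batch mean minus two sample (n - 1) standard
#' deviations of the detected-gene counts, computed once on the full
#' input batch. A sample passes iff its count is `>=` the threshold
#' (non-strict, so a zero-variance batch passes intact).
#'
#' @param gene_counts per-sample detected-gene counts (TPM > 1).
#' @return list with `pass` (logical vector) and `threshold`.
#' @export
qc_gene_count <- function(gene_counts) {
  if (length(gene_counts) < 2) {
    abort("gene-count QC needs a batch of at least 2 samples")
  }
  threshold <- mean(gene_counts) - 2 * sd(gene_counts)
  list(pass = gene_counts >= threshold, threshold = threshold)
}

#' Apply all QC criteria to a cohort
#'
#' Computes the three criteria, records them per sample in a QC report,
#' and returns the expression matrix restricted to samples passing all
#' three (column order preserved). The gene-count threshold is computed
#' once on the full input batch and frozen in the report.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param metadata sample metadata tibble with `sample_id` and
#'   `mapped_reads` (see [sample_metadata()]).
#' @param ercc_observed spike x sample matrix of observed ERCC TPM, or
#'   `NULL` to skip the ERCC criterion (recorded as pass).
#' @param ercc_expected tibble with `spike_id`, `concentration`.
#' @param min_reads mapped-read threshold (strictly greater to pass).
#' @param alpha ERCC correlation significance level.
#' @param detect_threshold TPM detection cutoff for the gene count.
#' @return list of class `qc_result`: `matrix` (filtered TPM) and
#'   `report` (tibble, one row per input sample).
#' @export
apply_qc <- function(tpm, metadata, ercc_observed = NULL,
                     ercc_expected = NULL, min_reads = 50000,
                     alpha = 0.05, detect_threshold = 1) {
  validate_expression_matrix(tpm, "TPM matrix")
  if (!all(colnames(tpm) %in% metadata$sample_id)) {
    abort("every matrix column needs a metadata row")
  }
  meta <- metadata[match(colnames(tpm), metadata$sample_id), ]
  reads_pass <- qc_reads(meta$mapped_reads, min_reads)

  if (is.null(ercc_observed)) {
    ercc <- tibble(ercc_r = NA_real_, ercc_p = NA_real_, ercc_pass = TRUE,
                   reason = NA_character_)[rep(1, ncol(tpm)), ]
  } else {
    if (is.null(ercc_expected)) {
      abort("ercc_expected is required with ercc_observed")
    }
    exp_conc <- ercc_expected$concentration[
      match(rownames(ercc_observed), ercc_expected$spike_id)
    ]
    if (anyNA(exp_conc)) abort("ERCC spikes missing from expected table")
    ercc <- purrr::map(colnames(tpm), function(s) {
      qc_ercc_correlation(ercc_observed[, s], exp_conc, alpha)
    }) |> bind_rows()
  }

  counts <- colSums(detection_matrix(tpm, detect_threshold))
  gc <- qc_gene_count(counts)

  report <- tibble(
    sample_id = colnames(tpm),
    mapped_reads = meta$mapped_reads,
    reads_pass = reads_pass,
    ercc_r = ercc$ercc_r, ercc_p = ercc$ercc_p,
    ercc_pass = ercc$ercc_pass, ercc_reason = ercc$reason,
    gene_count = counts,
    gene_count_threshold = gc$threshold,
    gene_pass = gc$pass,
    overall_pass = reads_pass & ercc$ercc_pass & gc$pass
  )
  if (!any(report$overall_pass)) abort("empty cohort: no sample passed QC")
  structure(
    list(matrix = tpm[, report$overall_pass, drop = FALSE],
         report = report),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %d of %d samples pass (reads %d, ERCC %d, genes %d)\n",
              sum(x$report$overall_pass), nrow(x$report),
              sum(x$report$reads_pass), sum(x$report$ercc_pass),
              sum(x$report$gene_pass)))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname tidiers
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_samples = nrow(x$report),
         n_pass = sum(x$report$overall_pass),
         gene_count_threshold = x$report$gene_count_threshold[1])
}

#' QC overview plot
#'
#' Detected-gene count against mapped reads, coloured by overall pass,
#' with the two corresponding thresholds drawn.
#'
#' @param object a `qc_result`.
#' @param min_reads threshold line for mapped reads.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.qc_result <- function(object, min_reads = 50000, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$mapped_reads,
                               y = .data$gene_count,
                               colour = .data$overall_pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$report$gene_count_threshold[1],
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = min_reads, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "uniquely mapped reads", y = "genes detected",
                  colour = "QC pass")
}
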