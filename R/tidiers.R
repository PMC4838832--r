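#' Tidiers for result objects
#'
#' `tidy()` returns the per-unit table of a result object (per sample,
#' per pool size, per edge); `glance()` returns a one-row summary.
#'
#' @param x a `qc_result`, `pooling_curve`, `de_result`,
#'   `pseudotime_result`, `ordering_robustness` or `gene_network`.
#' @param ... ignored.
#' @return a tibble.
#' @name tidiers
NULL
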