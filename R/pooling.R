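#' Synthetic pooling of nuclei against a bulk profile
#'
#' Repeatedly samples subsets of nuclei without replacement and asks what
#' fraction of the genes detected in bulk (bulk TPM > 1) are recovered by
#' the pool, where a gene counts as pool-detected when its TPM is > 0 in
#' at least one member. Up to `reps` distinct subsets are used per pool
#' size; when fewer distinct subsets exist the repetition count is
#' reduced to the number available (all subsets enumerated).
#'
#' @param single TPM matrix of single nuclei (genes x samples).
#' @param bulk named per-gene bulk TPM vector aligned on gene ids.
#' @param sizes pool sizes to evaluate; defaults to 1..ncol(single).
#' @param reps maximum distinct subsets per size.
#' @param seed integer seed (subset draws are deterministic given it).
#' @param denominator `"bulk"` divides the overlap by the bulk-detected
#'   set; `"union"` divides by the union of pool- and bulk-detected sets.
#' @return object of class `pooling_curve`: `curve` tibble (`size`,
#'   `mean_overlap`, `sd_overlap`, `n_subsets`), `final_overlap` at the
#'   full pool, `fisher_p` for the 2x2 detection table at the full pool,
#'   and `pearson_r` of pooled-mean vs bulk log2(TPM+1).
#' @export
synthetic_pool_overlap <- function(single, bulk, sizes = NULL, reps = 25,
                                   seed = 1,
                                   denominator = c("bulk", "union")) {
  validate_expression_matrix(single, "single-nucleus TPM")
  denominator <- match.arg(denominator)
  if (is.null(names(bulk)) || !all(rownames(single) %in% names(bulk))) {
    abort("bulk vector must be named and cover the matrix genes")
  }
  bulk <- bulk[rownames(single)]
  n <- ncol(single)
  sizes <- sizes %||% seq_len(n)
  if (any(sizes < 1 | sizes > n)) abort("pool sizes must be in 1..n")

  bulk_det <- bulk > 1
  if (!any(bulk_det)) abort("no bulk-detected genes (bulk TPM > 1)")
  det <- single > 0

  set.seed(seed)
  overlap_of <- function(members) {
    pool_det <- rowSums(det[, members, drop = FALSE]) > 0
    denom <- if (denominator == "bulk") sum(bulk_det) else
      sum(pool_det | bulk_det)
    sum(pool_det & bulk_det) / denom
  }
  curve <- purrr::map(sizes, function(s) {
    subsets <- draw_unique_subsets(n, s, reps)
    ov <- vapply(subsets, overlap_of, numeric(1))
    tibble(size = s, mean_overlap = mean(ov),
           sd_overlap = if (length(ov) > 1) sd(ov) else 0,
           n_subsets = length(subsets))
  }) |> bind_rows()

  pool_all <- rowSums(det) > 0
  tab <- table(factor(pool_all, c(TRUE, FALSE)),
               factor(bulk_det, c(TRUE, FALSE)))
  structure(
    list(curve = curve,
         final_overlap = overlap_of(seq_len(n)),
         fisher_p = fisher_exact_2x2(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2]),
         pearson_r = pool_bulk_correlation(single, bulk)$r,
         denominator = denominator),
    class = "pooling_curve"
  )
}

# Distinct size-s subsets of 1..n, at most `reps` of them. Full
# enumeration when the subset count is small (<= 10 * reps); otherwise
# rejection sampling on canonical sorted keys.
draw_unique_subsets <- function(n, s, reps) {
  total <- choose(n, s)
  if (total <= 10 * reps) {
    all_sub <- combn(n, s, simplify = FALSE)
    if (length(all_sub) <= reps) return(all_sub)
    return(all_sub[sample.int(length(all_sub), reps)])
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", reps)
  got <- 0L
  tries <- 0L
  while (got < reps && tries < 1000L * reps) {
    cand <- sort(sample.int(n, s))
    key <- paste(cand, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- cand
    }
    tries <- tries + 1L
  }
  out[seq_len(got)]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood method: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. A zero margin gives p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
}

#' Correlation between a pooled single-nucleus profile and bulk
#'
#' Pearson correlation of log2(TPM + 1) between the mean of the pooled
#' nuclei and the bulk profile, with the two-sided p from the t
#' transform.
#'
#' @param single TPM matrix of the pooled nuclei (genes x samples).
#' @param bulk named per-gene bulk TPM vector.
#' @return list with `r` and `p`.
#' @export
pool_bulk_correlation <- function(single, bulk) {
  validate_expression_matrix(single, "single-nucleus TPM")
  bulk <- bulk[rownames(single)]
  if (nrow(single) < 3) abort("need at least 3 genes")
  x <- log2p1(rowMeans(single))
  y <- log2p1(bulk)
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in pooled or bulk")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.pooling_curve <- function(x, ...) {
  cat(sprintf(
    "pooling curve over %d sizes; final overlap %.3f (denominator %s), Fisher p %.3g, Pearson r %.3f\n",
    nrow(x$curve), x$final_overlap, x$denominator, x$fisher_p, x$pearson_r
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pooling_curve <- function(x, ...) x$curve

#' @rdname tidiers
#' @export
glance.pooling_curve <- function(x, ...) {
  tibble(final_overlap = x$final_overlap, fisher_p = x$fisher_p,
         pearson_r = x$pearson_r, denominator = x$denominator)
}

#' Pooling-curve plot
#'
#' Mean overlap with the bulk-detected gene set as a function of pool
#' size, with +/- 1 SD ribbons.
#'
#' @param object a `pooling_curve`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.pooling_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$size, y = .data$mean_overlap)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_overlap - .data$sd_overlap),
                   ymax = pmin(1, .data$mean_overlap + .data$sd_overlap)),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nuclei pooled", y = "overlap with bulk-detected genes")
}
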