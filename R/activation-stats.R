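#' Per-group detection proportions for a gene
#'
#' Counts, per group, the samples in which the gene is detected at the
#' detection matrix's threshold (the pie-chart summaries of IEG
#' detection).
#'
#' @param det logical detection matrix from [detection_matrix()].
#' @param groups named character vector or factor mapping sample id to
#'   group label (names must cover every column of `det`).
#' @param gene gene id.
#' @return tibble with `group`, `k` (detected), `n`, `proportion`.
#' @export
detection_proportions <- function(det, groups, gene) {
  if (!gene %in% rownames(det)) abort(sprintf("unknown gene: %s", gene))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(det)) {
      abort("groups must be named by sample id or match column count")
    }
    names(groups) <- colnames(det)
  }
  if (!all(colnames(det) %in% names(groups))) {
    abort("every sample must be labelled")
  }
  g <- as.character(groups[colnames(det)])
  x <- det[gene, ]
  tibble(group = unique(g)) |>
    mutate(
      k = map_dbl(.data$group, ~ sum(x[g == .x])),
      n = map_dbl(.data$group, ~ sum(g == .x)),
      proportion = .data$k / .data$n
    )
}

#' Two-group test of equal proportions with Yates' correction
#'
#' The 2x2 chi-square test of equal proportions with continuity
#' correction, as in `prop.test(correct = TRUE)`: each cell contributes
#' `(max(0, |O - E| - 1/2))^2 / E`, p is the upper tail of chi-square
#' with 1 df, two-sided. When a table margin is zero the expected counts
#' degenerate; p is defined as 1 and flagged.
#'
#' @param k1,n1 detected count and group size, group 1.
#' @param k2,n2 detected count and group size, group 2.
#' @return one-row tibble: `k1`, `n1`, `k2`, `n2`, `p1_hat`, `p2_hat`,
#'   `chi2`, `p_value`, `degenerate`.
#' @export
prop_test_yates <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  out <- tibble(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                p1_hat = k1 / n1, p2_hat = k2 / n2,
                chi2 = NA_real_, p_value = NA_real_, degenerate = FALSE)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    out$chi2 <- 0
    out$p_value <- 1
    out$degenerate <- TRUE
    return(out)
  }
  pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  out$chi2 <- unname(pt$statistic)
  out$p_value <- pt$p.value
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= k) where X counts members of a `set_size`-gene set among
#' `draw_size` draws without replacement from a universe of `universe`
#' genes, summed exactly.
#'
#' @param k observed overlap.
#' @param set_size size of the annotated set (K).
#' @param draw_size number of draws (n).
#' @param universe universe size (N).
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(k, set_size, draw_size, universe) {
  if (k > min(set_size, draw_size) || set_size > universe ||
      draw_size > universe || k < 0) {
    abort("inconsistent hypergeometric sizes")
  }
  phyper(k - 1, set_size, universe - set_size, draw_size,
         lower.tail = FALSE)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution: with standardized
#' effect d and group sizes n1, n2, the noncentrality is
#' `d / sqrt(1/n1 + 1/n2)` on `n1 + n2 - 2` degrees of freedom.
#'
#' @param n1,n2 group sizes (each >= 2).
#' @param d standardized mean difference (Cohen's d).
#' @param alpha two-sided type-I rate.
#' @return attained power.
#' @export
t_test_power <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  nu <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  tc <- qt(1 - alpha / 2, nu)
  pt(tc, nu, ncp, lower.tail = FALSE) + pt(-tc, nu, ncp)
}

#' A-priori minimum sample sizes for a two-sample t-test
#'
#' Finds the smallest group sizes (n1, n2) with `n2 = ceiling(ratio *
#' n1)` whose two-sided two-sample t-test attains the target power at
#' effect size `d`, using the exact noncentral-t power (no normal
#' approximation).
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided type-I rate, in (0, 1).
#' @param power target power, in (0, 1).
#' @param ratio allocation ratio n2 / n1 (> 0).
#' @param max_n1 search bound.
#' @return one-row tibble: `n1`, `n2`, `power` attained.
#' @export
min_sample_size <- function(d, alpha = 0.05, power = 0.95, ratio = 1,
                            max_n1 = 1e6) {
  if (d <= 0) abort("effect size d must be > 0")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  if (ratio <= 0) abort("ratio must be > 0")
  for (n1 in 2:max_n1) {
    n2 <- max(2L, as.integer(ceiling(ratio * n1)))
    pw <- t_test_power(n1, n2, d, alpha)
    if (pw >= power) {
      return(tibble(n1 = n1, n2 = n2, power = pw))
    }
  }
  abort(sprintf("target power unreachable with n1 <= %d", max_n1))
}
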