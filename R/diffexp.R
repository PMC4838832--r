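#' Median-of-ratios size factors
#'
#' Per-sample scale factors relative to the geometric-mean reference
#' profile, computed over genes nonzero in every sample, then rescaled
#' to geometric mean 1. When no gene is nonzero in all samples the
#' factors fall back to total-count scaling (with a warning).
#'
#' @param counts count matrix (genes x samples); every sample must have
#'   at least one nonzero gene.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  validate_expression_matrix(counts, "count matrix")
  if (any(colSums(counts) == 0)) {
    abort("every sample needs at least one nonzero gene")
  }
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    warn("no gene nonzero in all samples; falling back to total-count scaling")
    sf <- colSums(counts)
  } else {
    sub <- counts[all_nonzero, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub / ref, 2, median)
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Moderated dispersion estimates
#'
#' Per-gene method-of-moments dispersion on normalized counts, pooled
#' within groups: `phi_hat = max(0, (s2 - m) / m^2)` with `m` the grand
#' mean and `s2` the pooled within-group variance. The common dispersion
#' is the median of `phi_hat` over genes with mean > 1, and per-gene
#' values are shrunk towards it with a prior weight of `prior_weight`
#' samples: `phi_g = (n * phi_hat + W * phi_common) / (n + W)`.
#' Degenerate genes (zero mean) take the common value.
#'
#' @param norm_counts normalized count matrix (genes x samples).
#' @param groups two-level group vector aligned with columns.
#' @param prior_weight shrinkage prior weight W, in samples.
#' @return list with `common` and `gene` (named per-gene vector).
#' @export
estimate_dispersion <- function(norm_counts, groups, prior_weight = 10) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (any(table(groups) < 2)) abort("need >= 2 samples per group")
  n <- ncol(norm_counts)
  k <- length(lv)
  ss <- 0
  for (g in lv) {
    sub <- norm_counts[, groups == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ss / (n - k)
  m <- rowMeans(norm_counts)
  phi_hat <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), NA_real_)
  informative <- !is.na(phi_hat) & m > 1
  if (!any(informative)) {
    abort("no gene with mean > 1; cannot estimate a common dispersion")
  }
  common <- median(phi_hat[informative])
  gene <- (n * phi_hat + prior_weight * common) / (n + prior_weight)
  gene[is.na(gene)] <- common
  list(common = common, gene = setNames(gene, rownames(norm_counts)))
}

#' Negative-binomial conditional exact test for two groups
#'
#' Counts are assumed equalized to a common effective library size. With
#' group sums SA, SB modelled as NB with sizes nA/phi, nB/phi and a
#' shared mean, the law of SA conditional on S = SA + SB is
#' beta-binomial(S, nA/phi, nB/phi); at phi = 0 it degenerates to
#' Binomial(S, nA / (nA + nB)). The two-sided p sums, over all s in
#' 0..S, the conditional probabilities no larger than that of the
#' observed split (minimum-likelihood two-sided rule).
#'
#' @param y1,y2 equalized integer count vectors for the two groups.
#' @param phi dispersion (>= 0).
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(y1, y2, phi) {
  stopifnot(phi >= 0, all(y1 >= 0), all(y2 >= 0))
  s1 <- sum(y1)
  s_tot <- s1 + sum(y2)
  if (s_tot == 0) return(1)
  n1 <- length(y1)
  n2 <- length(y2)
  logp <- conditional_log_probs(s_tot, n1, n2, phi)
  p_obs <- logp[s1 + 1]
  # ties up to relative 1e-7 count as "no more probable" (the base-R
  # binom.test convention, so the phi = 0 limit matches it exactly)
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

# log P(SA = s | S) for s = 0..S: binomial at phi = 0, beta-binomial
# with shapes n1/phi, n2/phi otherwise.
conditional_log_probs <- function(s_tot, n1, n2, phi) {
  s <- 0:s_tot
  if (phi == 0) {
    return(dbinom(s, s_tot, n1 / (n1 + n2), log = TRUE))
  }
  a <- n1 / phi
  b <- n2 / phi
  logw <- lgamma(s + a) - lfactorial(s) +
    lgamma(s_tot - s + b) - lfactorial(s_tot - s)
  logw - logsumexp(logw)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotone enforcement (`p.adjust`'s BH
#' method).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-group differential expression on expected counts
#'
#' The full pipeline: median-of-ratios size factors, equalization of
#' counts to a common effective library size (normalized counts rounded
#' half-up), moderated method-of-moments dispersion, a per-gene
#' negative-binomial conditional exact test, and Benjamini-Hochberg
#' adjustment. Expected counts may be non-integer; they are rounded only
#' after normalization.
#'
#' @param counts expected-count matrix (genes x samples).
#' @param metadata sample metadata tibble with `sample_id` and the
#'   grouping column.
#' @param group_col name of the two-level grouping column (default
#'   `"stain"`).
#' @param exclude optional logical vector or column name flagging
#'   samples to drop before testing (e.g. pseudo-FOS+ nuclei).
#' @param prior_weight dispersion shrinkage weight (see
#'   [estimate_dispersion()]).
#' @return tibble of class `de_result`, sorted by `q` then `p`, with
#'   per-gene normalized group means, `log_fc` (log2, group2 over
#'   group1), `dispersion`, `p`, `q` and `direction`; group identities
#'   in attributes `group1`/`group2`.
#' @export
run_de <- function(counts, metadata, group_col = "stain", exclude = NULL,
                   prior_weight = 10) {
  validate_expression_matrix(counts, "count matrix")
  meta <- metadata[match(colnames(counts), metadata$sample_id), ]
  keep <- rep(TRUE, ncol(counts))
  if (!is.null(exclude)) {
    flag <- if (is.character(exclude) && length(exclude) == 1) {
      meta[[exclude]]
    } else {
      exclude
    }
    keep <- !(flag %in% TRUE)
  }
  counts <- counts[, keep, drop = FALSE]
  groups <- as.character(meta[[group_col]][keep])
  lv <- sort(unique(groups))
  if (length(lv) != 2) abort("run_de() needs exactly two groups")
  if (any(table(groups) < 2)) abort("each group needs >= 2 samples")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  eq <- floor(norm + 0.5)                 # round half-up
  disp <- estimate_dispersion(norm, groups, prior_weight)

  i1 <- groups == lv[1]
  i2 <- groups == lv[2]
  p <- vapply(seq_len(nrow(eq)), function(g) {
    nb_exact_test(eq[g, i1], eq[g, i2], disp$gene[g])
  }, numeric(1))

  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  res <- tibble(
    gene_id = rownames(counts),
    mean_1 = m1, mean_2 = m2,
    log_fc = log2((m2 + 0.5) / (m1 + 0.5)),
    dispersion = unname(disp$gene),
    p = p, q = bh_adjust(p),
    direction = ifelse(m2 >= m1, lv[2], lv[1])
  ) |>
    arrange(.data$q, .data$p)
  attr(res, "group1") <- lv[1]
  attr(res, "group2") <- lv[2]
  attr(res, "common_dispersion") <- disp$common
  class(res) <- c("de_result", class(res))
  res
}

#' @rdname tidiers
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_q_05 = sum(x$q < 0.05),
         n_q_01 = sum(x$q < 0.01),
         common_dispersion = attr(x, "common_dispersion"))
}

#' Differential-expression volcano plot
#'
#' @param object a `de_result`.
#' @param fdr highlight threshold on `q`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, fdr = 0.05, ...) {
  dat <- mutate(as_tibble(object), significant = .data$q < fdr)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log_fc,
                                    y = -log10(pmax(.data$p, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("log2 fold-change (%s / %s)",
                  attr(object, "group2"), attr(object, "group1")),
      y = "-log10 p", colour = sprintf("q < %g", fdr)
    )
}
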