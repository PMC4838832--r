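#' Select genes for supervised ordering
#'
#' Genes differentially expressed between the stain groups at an
#' adjusted p strictly below `padj_threshold`, in the order they appear
#' in the DE table.
#'
#' @param de a `de_result` from [run_de()].
#' @param padj_threshold adjusted-p cutoff (strict `<`).
#' @return character vector of gene ids.
#' @export
supervised_gene_filter <- function(de, padj_threshold = 0.01) {
  genes <- de$gene_id[de$q < padj_threshold]
  if (length(genes) == 0) {
    abort(sprintf(
      "no gene passes adjusted p < %g; consider raising the threshold",
      padj_threshold
    ))
  }
  genes
}

#' Independent-component embedding of samples
#'
#' Z-scores each gene across samples, whitens to `n_components`
#' principal directions and runs fixed-point ICA (symmetric FastICA,
#' tanh contrast). Components are ordered by the one-way F statistic of
#' their association with the stain label (descending) and oriented so
#' the FOS+ group mean is positive; without labels they are ordered by
#' excess kurtosis and oriented to positive skewness.
#'
#' @param expr log2(TPM+1) matrix on the filtered genes
#'   (genes x samples).
#' @param stain optional named stain labels (`"FOS_POS"`/`"FOS_NEG"`).
#' @param n_components number of components (default 2).
#' @param seed integer seed; the embedding is deterministic given it.
#' @return samples x components coordinate matrix.
#' @export
reduce_ica <- function(expr, stain = NULL, n_components = 2, seed = 1) {
  if (ncol(expr) < n_components + 1) {
    abort("need more samples than components")
  }
  v <- apply(expr, 1, var)
  expr <- expr[v > 0, , drop = FALSE]
  if (nrow(expr) < n_components) abort("too few informative genes")
  Xz <- t(scale(t(expr)))            # z-score per gene
  S <- fastica_sources(t(Xz), n_components, seed = seed)

  if (!is.null(stain)) {
    stain <- stain_for(colnames(expr), stain)
    stat <- apply(S, 2, function(s) f_statistic(s, stain)$statistic)
    S <- S[, order(stat, decreasing = TRUE), drop = FALSE]
    pos <- stain == "FOS_POS"
    for (j in seq_len(ncol(S))) {
      if (mean(S[pos, j]) < mean(S[!pos, j])) S[, j] <- -S[, j]
    }
  } else {
    kurt <- apply(S, 2, function(s) mean((s - mean(s))^4) / var(s)^2 - 3)
    S <- S[, order(kurt, decreasing = TRUE), drop = FALSE]
    for (j in seq_len(ncol(S))) {
      if (mean((S[, j] - mean(S[, j]))^3) < 0) S[, j] <- -S[, j]
    }
  }
  colnames(S) <- paste0("IC", seq_len(ncol(S)))
  S
}

stain_for <- function(sample_ids, stain) {
  if (is.null(names(stain))) {
    if (length(stain) != length(sample_ids)) {
      abort("stain must be named by sample id or aligned to samples")
    }
    names(stain) <- sample_ids
  }
  as.character(stain[sample_ids])
}

f_statistic <- function(values, groups) {
  fit <- anova(lm(values ~ factor(groups)))
  list(statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1])
}

#' Pseudotemporal ordering along the MST diameter path
#'
#' Builds the Euclidean minimum spanning tree of the component
#' coordinates (Kruskal, ties broken lexicographically on sample-id
#' pairs), takes the maximum-weight leaf-to-leaf path (the tree
#' diameter) as the main trajectory, roots it at the endpoint with the
#' lower root-marker expression, and sets each on-path sample's
#' pseudotime to its cumulative path distance from the root, normalized
#' to \[0, 1\]. Off-path samples attach at the nearest path node in tree
#' distance and inherit its pseudotime.
#'
#' @param coords samples x 2 coordinate matrix with sample-id rownames
#'   (from [reduce_ica()]).
#' @param root_marker named per-sample scalar used only to orient the
#'   path (e.g. mean IEG-panel log-expression); pseudotime increases away
#'   from the endpoint with the lower value.
#' @return object of class `pseudotime_result`: `samples` tibble
#'   (`sample_id`, `ic1`, `ic2`, `pseudotime`, `on_main_path`, `cluster`,
#'   `pseudo_positive`), the `tree` (igraph), the ordered `path`, and the
#'   MST `edges` tibble.
#' @export
build_mst_order <- function(coords, root_marker) {
  if (nrow(coords) < 3) abort("need at least 3 samples")
  ids <- rownames(coords)
  if (is.null(ids)) abort("coords must have sample-id rownames")
  root_marker <- root_marker[ids]
  if (anyNA(root_marker)) abort("root_marker must cover every sample")

  edges <- mst_kruskal(coords)
  if (all(edges$weight == 0)) {
    abort("identical coordinates for all samples: zero-length diameter")
  }
  tree <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = ids)
  d <- igraph::distances(tree, weights = igraph::E(tree)$weight)

  # diameter endpoints: maximum pairwise tree distance, lexicographic
  # tie-break on the sorted id pair
  cand <- which(d == max(d), arr.ind = TRUE)
  pairs <- t(apply(cand, 1, function(ij) sort(ids[ij])))
  best <- order(pairs[, 1], pairs[, 2])[1]
  ends <- pairs[best, ]
  root <- ends[which.min(root_marker[ends])]
  tip <- setdiff(ends, root)

  path <- igraph::shortest_paths(tree, from = root, to = tip,
                                 weights = igraph::E(tree)$weight)
  path <- names(path$vpath[[1]])
  cum <- c(0, cumsum(d[cbind(path[-length(path)], path[-1])]))
  pt_path <- setNames(cum / max(cum), path)

  pt <- setNames(rep(NA_real_, length(ids)), ids)
  pt[path] <- pt_path
  on_path <- ids %in% path
  off <- ids[!on_path]
  if (length(off)) {
    d_off <- d[off, path, drop = FALSE]
    for (s in off) {
      nearest <- path[order(d_off[s, ], path)[1]]
      pt[s] <- pt_path[nearest]
    }
  }

  structure(
    list(
      samples = tibble(
        sample_id = ids,
        ic1 = coords[, 1],
        ic2 = if (ncol(coords) > 1) coords[, 2] else NA_real_,
        pseudotime = unname(pt),
        on_main_path = on_path,
        cluster = NA_character_,
        pseudo_positive = NA
      ),
      tree = tree, path = path, edges = edges
    ),
    class = "pseudotime_result"
  )
}

# Kruskal MST on Euclidean distances; ties broken by the lexicographic
# sorted sample-id pair so the tree is deterministic.
mst_kruskal <- function(coords) {
  ids <- rownames(coords)
  n <- nrow(coords)
  pair <- t(combn(n, 2))
  w <- sqrt(rowSums((coords[pair[, 1], , drop = FALSE] -
                       coords[pair[, 2], , drop = FALSE])^2))
  a <- pmin(ids[pair[, 1]], ids[pair[, 2]])
  b <- pmax(ids[pair[, 1]], ids[pair[, 2]])
  ord <- order(w, a, b)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- integer(0)
  for (e in ord) {
    ra <- find(pair[e, 1])
    rb <- find(pair[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      keep <- c(keep, e)
      if (length(keep) == n - 1) break
    }
  }
  tibble(from = ids[pair[keep, 1]], to = ids[pair[keep, 2]],
         weight = w[keep])
}

#' Cut the MST into k clusters
#'
#' Removes the k - 1 longest tree edges (ties broken lexicographically
#' on the sample-id pair); the connected components are the clusters,
#' labelled `C1..Ck` by ascending mean pseudotime.
#'
#' @param result a `pseudotime_result`.
#' @param k number of clusters (default 5).
#' @return the result with `samples$cluster` filled in.
#' @export
assign_clusters <- function(result, k = 5) {
  stopifnot(inherits(result, "pseudotime_result"))
  n <- nrow(result$samples)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort("k cannot exceed the number of samples")
  edges <- result$edges |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    arrange(dplyr::desc(.data$weight), .data$a, .data$b)
  cut <- edges[seq_len(min(k - 1, nrow(edges))), ]
  kept <- dplyr::anti_join(result$edges, cut,
                           by = c("from", "to", "weight"))
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = result$samples$sample_id)
  comp <- igraph::components(g)$membership
  mean_pt <- tapply(result$samples$pseudotime,
                    comp[result$samples$sample_id], mean)
  relabel <- setNames(sprintf("C%d", rank(mean_pt, ties.method = "first")),
                      names(mean_pt))
  result$samples$cluster <-
    unname(relabel[as.character(comp[result$samples$sample_id])])
  result
}

#' Flag pseudo-FOS+ nuclei
#'
#' A cluster is FOS-minus-majority when more than half its members are
#' FOS-; a nucleus is pseudo-FOS+ when it stains FOS+ but sits in such a
#' cluster (high FOS protein, unresponsive transcriptome).
#'
#' @param result a clustered `pseudotime_result`.
#' @param stain named stain labels (`"FOS_POS"`/`"FOS_NEG"`).
#' @return the result with `samples$pseudo_positive` filled in.
#' @export
flag_pseudo_positive <- function(result, stain) {
  stopifnot(inherits(result, "pseudotime_result"))
  if (anyNA(result$samples$cluster)) {
    abort("assign clusters before flagging pseudo-FOS+ nuclei")
  }
  st <- stain_for(result$samples$sample_id, stain)
  neg_majority <- result$samples |>
    mutate(stain = st) |>
    group_by(.data$cluster) |>
    summarise(neg_maj = mean(.data$stain == "FOS_NEG") > 0.5)
  result$samples <- result$samples |>
    left_join(neg_majority, by = "cluster") |>
    mutate(pseudo_positive = st == "FOS_POS" & .data$neg_maj) |>
    select(-"neg_maj")
  result
}

#' One-way F-test of a scalar against stain
#'
#' One-way ANOVA of a per-sample value (a component coordinate or the
#' pseudotime) on the stain label.
#'
#' @param values numeric per-sample vector.
#' @param stain group labels aligned with `values`.
#' @return one-row tibble with `statistic` and `p_value`.
#' @export
stain_association <- function(values, stain) {
  stain <- as.character(stain)
  tab <- table(stain)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 members each")
  }
  fs <- f_statistic(values, stain)
  tibble(statistic = fs$statistic, p_value = fs$p)
}

#' Per-gene regression of expression on pseudotime
#'
#' Simple linear regression of log2(TPM+1) on pseudotime for each gene,
#' by default over main-trajectory samples only, with the F-test for the
#' slope and BH adjustment across genes. Constant genes get p = 1.
#'
#' @param expr log2(TPM+1) matrix (genes x samples).
#' @param result a `pseudotime_result` covering the samples.
#' @param on_path_only restrict to main-trajectory samples.
#' @return tibble: `gene_id`, `slope`, `statistic`, `p`, `q`.
#' @export
gene_pseudotime_regression <- function(expr, result, on_path_only = TRUE) {
  stopifnot(inherits(result, "pseudotime_result"))
  samp <- result$samples
  if (on_path_only) samp <- samp[samp$on_main_path, ]
  if (nrow(samp) < 3) abort("need >= 3 samples for regression")
  x <- setNames(samp$pseudotime, samp$sample_id)
  regress_matrix(expr[, names(x), drop = FALSE], x)
}

#' Per-gene comparison of one cluster against the rest
#'
#' Regresses each gene's log2(TPM+1) on the indicator of membership in
#' the target cluster (equivalently a pooled-variance two-sample test via
#' the linear-model F statistic), with BH adjustment across genes.
#'
#' @param expr log2(TPM+1) matrix (genes x samples).
#' @param result a clustered `pseudotime_result`.
#' @param target cluster label to contrast against all other samples.
#' @return tibble: `gene_id`, `slope` (mean difference), `statistic`,
#'   `p`, `q`.
#' @export
cluster_vs_rest_regression <- function(expr, result, target) {
  stopifnot(inherits(result, "pseudotime_result"))
  memb <- result$samples$cluster == target
  if (!any(memb) || all(memb)) {
    abort("target cluster must be non-empty and not all samples")
  }
  x <- setNames(as.numeric(memb), result$samples$sample_id)
  regress_matrix(expr[, names(x), drop = FALSE], x)
}

# Vectorized simple linear regression of each matrix row on x.
regress_matrix <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) abort("degenerate predictor: no variation")
  slope <- as.numeric(Y %*% xc) / sxx
  yc <- Y - rowMeans(Y)
  sst <- rowSums(yc^2)
  ssr <- slope^2 * sxx
  sse <- pmax(sst - ssr, 0)
  fstat <- ifelse(sst > 0, ssr / (sse / (n - 2)), NA_real_)
  p <- ifelse(sst > 0, pf(fstat, 1, n - 2, lower.tail = FALSE), 1)
  p[!is.finite(p)] <- 0        # perfect fit: sse = 0
  tibble(gene_id = rownames(Y), slope = unname(slope),
         statistic = unname(fstat), p = unname(p), q = bh_adjust(unname(p)))
}

#' Supervised pseudotime pipeline
#'
#' Convenience wrapper: filter genes from the DE table (adjusted p <
#' `padj_threshold`), embed samples with [reduce_ica()], order them with
#' [build_mst_order()] rooted at low mean expression of the
#' `root_markers` panel, cut `k` clusters and flag pseudo-FOS+ nuclei.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param de `de_result` used for the supervised gene filter.
#' @param metadata metadata tibble with `sample_id` and `stain`.
#' @param root_markers gene ids whose mean log-expression orients the
#'   path (low end = root); defaults to the 10 strongest DE genes higher
#'   in FOS+.
#' @param padj_threshold supervised filter cutoff.
#' @param k number of MST clusters.
#' @param n_components ICA dimensionality.
#' @param seed integer seed.
#' @return a `pseudotime_result` with `genes_used` attached.
#' @export
order_pseudotime <- function(tpm, de, metadata, root_markers = NULL,
                             padj_threshold = 0.01, k = 5,
                             n_components = 2, seed = 1) {
  genes <- supervised_gene_filter(de, padj_threshold)
  stain <- setNames(metadata$stain, metadata$sample_id)
  expr <- log2p1(tpm[genes, , drop = FALSE])
  coords <- reduce_ica(expr, stain = stain, n_components = n_components,
                       seed = seed)
  if (is.null(root_markers)) {
    up <- de |>
      filter(.data$direction == "FOS_POS") |>
      arrange(.data$q, .data$p)
    root_markers <- head(up$gene_id, 10)
  }
  marker <- colMeans(log2p1(tpm[root_markers, , drop = FALSE]))
  res <- build_mst_order(coords, marker)
  res <- assign_clusters(res, k = min(k, nrow(res$samples)))
  res <- flag_pseudo_positive(res, stain)
  res$genes_used <- genes
  res$root_markers <- root_markers
  res
}

#' Leave-one-out robustness of the ordering
#'
#' Recomputes the ICA embedding and MST ordering with each sample left
#' out in turn (over a fixed supervised gene set) and reports the
#' absolute Spearman correlation between full and reduced pseudotimes on
#' the shared samples; the absolute value absorbs orientation flips.
#'
#' @param expr log2(TPM+1) matrix on the filtered genes.
#' @param root_marker named per-sample orientation scalar (see
#'   [build_mst_order()]).
#' @param stain optional stain labels for component ordering.
#' @param n_components ICA dimensionality.
#' @param seed integer seed.
#' @return tibble of class `ordering_robustness`: `left_out`,
#'   `spearman_abs`; summary via `glance()`.
#' @export
loo_robustness <- function(expr, root_marker, stain = NULL,
                           n_components = 2, seed = 1) {
  n <- ncol(expr)
  if (n < 4) abort("need at least 4 samples")
  full <- build_mst_order(
    reduce_ica(expr, stain = stain, n_components = n_components,
               seed = seed),
    root_marker
  )
  pt_full <- setNames(full$samples$pseudotime, full$samples$sample_id)
  rows <- purrr::map(seq_len(n), function(i) {
    sub <- expr[, -i, drop = FALSE]
    red <- build_mst_order(
      reduce_ica(sub, stain = stain, n_components = n_components,
                 seed = seed),
      root_marker
    )
    shared <- red$samples$sample_id
    rho <- suppressWarnings(cor(pt_full[shared], red$samples$pseudotime,
                                method = "spearman"))
    tibble(left_out = colnames(expr)[i], spearman_abs = abs(rho))
  })
  out <- bind_rows(rows)
  class(out) <- c("ordering_robustness", class(out))
  out
}

#' @rdname tidiers
#' @export
glance.ordering_robustness <- function(x, ...) {
  tibble(n = nrow(x), min_rho = min(x$spearman_abs),
         mean_rho = mean(x$spearman_abs))
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf(
    "pseudotime over %d samples (%d on the main path%s)\n",
    nrow(x$samples), sum(x$samples$on_main_path),
    if (!anyNA(x$samples$cluster)) {
      sprintf(", %d clusters", length(unique(x$samples$cluster)))
    } else ""
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pseudotime_result <- function(x, ...) x$samples

#' @rdname tidiers
#' @export
glance.pseudotime_result <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_on_path = sum(x$samples$on_main_path),
         n_clusters = length(unique(stats::na.omit(x$samples$cluster))),
         n_pseudo_positive = sum(x$samples$pseudo_positive %in% TRUE))
}

#' Pseudotime embedding plot
#'
#' Samples in component space coloured by pseudotime (or cluster), with
#' the MST drawn and the main trajectory emphasised.
#'
#' @param object a `pseudotime_result`.
#' @param colour `"pseudotime"` or `"cluster"`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.pseudotime_result <- function(object,
                                       colour = c("pseudotime", "cluster"),
                                       ...) {
  colour <- match.arg(colour)
  samp <- object$samples
  seg <- object$edges |>
    left_join(samp |> select("sample_id", x1 = "ic1", y1 = "ic2"),
              by = c(from = "sample_id")) |>
    left_join(samp |> select("sample_id", x2 = "ic1", y2 = "ic2"),
              by = c(to = "sample_id")) |>
    mutate(on_path = .data$from %in% object$path &
             .data$to %in% object$path)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, linewidth = .data$on_path),
      colour = "grey60"
    ) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3,
                                               `TRUE` = 1.1),
                                    guide = "none") +
    ggplot2::geom_point(
      data = samp,
      ggplot2::aes(x = .data$ic1, y = .data$ic2,
                   colour = .data[[colour]])
    ) +
    ggplot2::labs(x = "IC1", y = "IC2")
}
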