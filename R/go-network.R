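#' Per-term parent-count weights
#'
#' Each ontology term is weighted by its number of parents: either the
#' immediate (`"direct"`) parents or all distinct ancestors under the
#' transitive closure (`"ancestors"`). Root terms weigh 0. The parent
#' graph must be acyclic.
#'
#' @param parents tibble with columns `term` and `parent`; roots may be
#'   listed with `NA` parents or simply omitted from the `term` column.
#' @param mode `"direct"` or `"ancestors"`.
#' @return named numeric vector of weights for every term appearing in
#'   the table (as child or parent).
#' @export
parent_weights <- function(parents, mode = c("direct", "ancestors")) {
  mode <- match.arg(mode)
  parents <- parents |> filter(!is.na(.data$parent))
  terms <- unique(c(parents$term, parents$parent))
  if (nrow(parents)) {
    g <- igraph::graph_from_data_frame(
      parents[, c("term", "parent")], directed = TRUE, vertices = terms
    )
    if (!igraph::is_dag(g)) abort("cycle detected in the parent graph")
  }
  w <- setNames(rep(0, length(terms)), terms)
  if (!nrow(parents)) return(w)
  if (mode == "direct") {
    tab <- table(parents$term)
    w[names(tab)] <- as.numeric(tab)
  } else {
    for (term in terms) {
      anc <- igraph::subcomponent(g, term, mode = "out")
      w[term] <- length(anc) - 1   # exclude the term itself
    }
  }
  w
}

#' Weighted cosine similarity of two binary annotation vectors
#'
#' `sum(w x y) / sqrt(sum(w x^2) * sum(w y^2))`, with weights entering
#' the inner product linearly; 0 when either weighted norm vanishes.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length.
#' @param w non-negative per-position weights.
#' @return similarity in \[0, 1\].
#' @export
weighted_cosine <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    abort("x, y and w must have equal lengths")
  }
  if (any(w < 0)) abort("weights must be non-negative")
  x <- as.numeric(x)
  y <- as.numeric(y)
  nx <- sum(w * x^2)
  ny <- sum(w * y^2)
  if (nx == 0 || ny == 0) return(0)
  sum(w * x * y) / sqrt(nx * ny)
}

#' Parent-weighted GO cosine-similarity gene network
#'
#' Builds the gene-by-term binary annotation matrix, weights each term
#' column by its parent count, computes all pairwise weighted cosine
#' similarities and keeps edges strictly above `threshold`. Edge
#' distance is `1 - similarity` (the scale on which the network is
#' drawn). Genes without usable annotations are listed as isolated
#' nodes.
#'
#' @param annotations tibble with columns `gene` and `term`.
#' @param parents term-parent tibble (see [parent_weights()]).
#' @param threshold similarity cutoff (strict `>`; default 0.5).
#' @param weight_mode passed to [parent_weights()].
#' @param genes optional gene universe; defaults to annotated genes.
#' @return object of class `gene_network`: `edges` tibble (`gene1`,
#'   `gene2`, `similarity`, `distance`), `isolated` genes, `threshold`,
#'   `weights`.
#' @export
build_go_network <- function(annotations, parents, threshold = 0.5,
                             weight_mode = c("direct", "ancestors"),
                             genes = NULL) {
  weight_mode <- match.arg(weight_mode)
  genes <- genes %||% sort(unique(annotations$gene))
  if (length(genes) < 2) abort("need at least 2 genes")
  w_all <- parent_weights(parents, weight_mode)
  terms <- sort(unique(annotations$term))
  missing <- setdiff(terms, names(w_all))
  # terms absent from the parent table are treated as roots (weight 0)
  w <- c(w_all, setNames(rep(0, length(missing)), missing))[terms]

  X <- matrix(0, length(genes), length(terms),
              dimnames = list(genes, terms))
  ann <- annotations |> filter(.data$gene %in% genes)
  X[cbind(ann$gene, ann$term)] <- 1

  Xw <- sweep(X, 2, w, `*`)
  ip <- Xw %*% t(X)                    # weighted inner products
  nrm <- sqrt(diag(ip))
  annotated <- nrm > 0
  sim <- ip / outer(nrm, nrm)
  sim[!annotated, ] <- 0
  sim[, !annotated] <- 0

  idx <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  edges <- tibble(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    similarity = sim[idx], distance = 1 - sim[idx]
  ) |> arrange(.data$gene1, .data$gene2)
  connected <- unique(c(edges$gene1, edges$gene2))
  structure(
    list(edges = edges, isolated = setdiff(genes, connected),
         threshold = threshold, weight_mode = weight_mode,
         weights = w),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "GO similarity network: %d edges (> %g), %d isolated genes, %s weights\n",
    nrow(x$edges), x$threshold, length(x$isolated), x$weight_mode
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.gene_network <- function(x, ...) x$edges

#' @rdname tidiers
#' @export
glance.gene_network <- function(x, ...) {
  tibble(n_edges = nrow(x$edges), n_isolated = length(x$isolated),
         threshold = x$threshold, weight_mode = x$weight_mode)
}

#' Export a gene network
#'
#' `write_edge_list()` writes the TSV edge list (gene1, gene2,
#' similarity, distance); `write_graphml()` exports GraphML with the
#' distance as edge weight, for Cytoscape-style layout tools.
#'
#' @param network a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  nodes <- unique(c(network$edges$gene1, network$edges$gene2,
                    network$isolated))
  g <- igraph::graph_from_data_frame(
    network$edges |>
      rename(from = "gene1", to = "gene2", weight = "distance"),
    directed = FALSE, vertices = nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Network plot on the distance scale
#'
#' @param object a `gene_network`.
#' @param seed layout seed.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.gene_network <- function(object, seed = 1, ...) {
  nodes <- unique(c(object$edges$gene1, object$edges$gene2,
                    object$isolated))
  g <- igraph::graph_from_data_frame(
    object$edges |> rename(from = "gene1", to = "gene2"),
    directed = FALSE, vertices = nodes
  )
  set.seed(seed)
  xy <- igraph::layout_with_fr(
    g, weights = 1 / (object$edges$distance + 0.05)
  )
  lay <- tibble(gene = nodes, x = xy[, 1], y = xy[, 2])
  seg <- object$edges |>
    left_join(lay, by = c(gene1 = "gene")) |>
    rename(x1 = "x", y1 = "y") |>
    left_join(lay, by = c(gene2 = "gene")) |>
    rename(x2 = "x", y2 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, alpha = .data$similarity),
      colour = "grey50"
    ) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::theme_void()
}
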