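test_that("the supervised gene filter is strict at its threshold", {
  de <- tibble::tibble(gene_id = c("a", "b", "c"),
                       q = c(0.005, 0.01, 0.5))
  class(de) <- c("de_result", class(de))
  expect_identical(supervised_gene_filter(de, 0.01), "a")
  expect_identical(supervised_gene_filter(de, 1.0), c("a", "b", "c"))
  expect_error(supervised_gene_filter(de, 1e-6), "no gene")
})

test_that("ICA recovers a one-dimensional continuum for any seed", {
  lf <- line_expr()
  stain <- setNames(ifelse(lf$pos > median(lf$pos), "FOS_POS",
                           "FOS_NEG"), colnames(lf$expr))
  for (s in 1:4) {
    coords <- reduce_ica(lf$expr, stain = stain, seed = s)
    expect_gt(abs(cor(coords[, 1], lf$pos, method = "spearman")), 0.99)
  }
  expect_error(reduce_ica(lf$expr[, 1:2]), "more samples")
})

test_that("ICA component 1 separates well-separated groups and respects duplicates", {
  set.seed(5)
  n <- 40
  shift <- rep(c(0, 4), each = n / 2)
  m <- matrix(rnorm(30 * n), 30, n) +
    matrix(rep(shift, each = 30) * rnorm(30, 1, 0.1), 30, n)
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:n))
  stain <- setNames(rep(c("FOS_NEG", "FOS_POS"), each = n / 2),
                    colnames(m))
  coords <- reduce_ica(m, stain = stain, seed = 1)
  expect_lt(stain_association(coords[, 1], stain)$p_value, 1e-6)
  # FOS+ oriented positive on each component
  expect_gt(mean(coords[stain == "FOS_POS", 1]),
            mean(coords[stain == "FOS_NEG", 1]))

  dup <- cbind(m, m)
  colnames(dup) <- c(colnames(m), paste0(colnames(m), "_dup"))
  cd <- reduce_ica(dup, stain = setNames(rep(stain, 2), colnames(dup)),
                   seed = 1)
  expect_equal(unname(cd[1:n, ]), unname(cd[n + 1:n, ]),
               tolerance = 1e-8)
})

test_that("collinear points get evenly spaced pseudotime and orientation follows the marker", {
  coords <- cbind(x = c(0, 1, 2, 3, 4), y = rep(0, 5))
  rownames(coords) <- paste0("s", 1:5)
  marker <- setNames(1:5, rownames(coords))
  res <- build_mst_order(coords, marker)
  expect_equal(
    setNames(res$samples$pseudotime, res$samples$sample_id)[paste0("s", 1:5)],
    setNames(c(0, 0.25, 0.5, 0.75, 1), paste0("s", 1:5))
  )
  expect_true(all(res$samples$on_main_path))

  rev <- build_mst_order(coords, setNames(5:1, rownames(coords)))
  expect_equal(rev$samples$pseudotime, 1 - res$samples$pseudotime)

  same <- coords; same[, 1] <- 0
  expect_error(build_mst_order(same, marker), "zero-length")
})

test_that("branch samples are flagged off-path and inherit the junction pseudotime", {
  # main path along x with a short spur rising from its midpoint
  coords <- rbind(
    a = c(0, 0), b = c(1, 0), c = c(2, 0), d = c(3, 0), e = c(4, 0),
    f = c(2, 0.8), g = c(2, 1.6)
  )
  marker <- setNames(c(1, 2, 3, 4, 5, 3, 3), rownames(coords))
  res <- build_mst_order(coords, marker)
  samp <- res$samples
  expect_identical(sort(res$path), sort(c("a", "b", "c", "d", "e")))
  expect_false(any(samp$on_main_path[samp$sample_id %in% c("f", "g")]))
  expect_equal(samp$pseudotime[samp$sample_id == "f"], 0.5)
  expect_equal(samp$pseudotime[samp$sample_id == "g"], 0.5)
})

test_that("cutting the longest tree edges recovers separated blobs", {
  set.seed(6)
  blob1 <- cbind(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1))
  blob2 <- cbind(rnorm(10, 5, 0.1), rnorm(10, 0, 0.1))
  coords <- rbind(blob1, blob2)
  rownames(coords) <- sprintf("s%02d", 1:20)
  marker <- setNames(coords[, 1], rownames(coords))
  res <- build_mst_order(coords, marker)

  one <- assign_clusters(res, k = 1)
  expect_equal(length(unique(one$samples$cluster)), 1)

  two <- assign_clusters(res, k = 2)
  cl <- two$samples$cluster
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_false(cl[1] == cl[11])

  all_own <- assign_clusters(res, k = 20)
  expect_equal(length(unique(all_own$samples$cluster)), 20)
  expect_error(assign_clusters(res, k = 0), "k must be")
})

test_that("pseudo-FOS+ flags follow the majority rule exactly", {
  coords <- cbind(c(0, 1, 2, 3, 10, 11, 12), rep(0, 7))
  rownames(coords) <- paste0("s", 1:7)
  marker <- setNames(coords[, 1], rownames(coords))
  res <- assign_clusters(build_mst_order(coords, marker), k = 2)
  # first cluster: 3 FOS-, 1 FOS+ (pseudo); second: pure FOS+
  stain <- setNames(c("FOS_NEG", "FOS_NEG", "FOS_NEG", "FOS_POS",
                      "FOS_POS", "FOS_POS", "FOS_POS"),
                    rownames(coords))
  res <- flag_pseudo_positive(res, stain)
  flags <- setNames(res$samples$pseudo_positive, res$samples$sample_id)
  expect_true(flags[["s4"]])
  expect_false(any(flags[c("s1", "s2", "s3", "s5", "s6", "s7")]))

  # single mixed cluster: every FOS+ flagged iff FOS- is the majority
  single <- assign_clusters(build_mst_order(coords, marker), k = 1)
  single <- flag_pseudo_positive(single, stain)
  expect_false(any(single$samples$pseudo_positive))  # 4/7 FOS+
})

test_that("noise-relabelled nuclei are recovered by the pseudo-FOS+ flag", {
  co <- cohort_default()
  pt <- pt_default()
  truth <- co$truth$samples
  j <- merge(pt$samples, truth[, c("sample_id", "relabelled")],
             by = "sample_id")
  expect_gte(sum(j$pseudo_positive & j$relabelled) /
               max(1, sum(j$relabelled)), 0.7)
})

test_that("stain association matches a hand ANOVA and detects separation", {
  # mirrored construction: both groups share mean and spread
  mirror <- c(-1, 0, 1, -1, 0, 1)
  g <- rep(c("FOS_NEG", "FOS_POS"), each = 3)
  res <- stain_association(mirror, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # six-value hand oracle via explicit sums of squares
  v <- c(1, 2, 3, 6, 7, 11)
  m1 <- mean(v[1:3]); m2 <- mean(v[4:6]); mg <- mean(v)
  ssb <- 3 * (m1 - mg)^2 + 3 * (m2 - mg)^2
  ssw <- sum((v[1:3] - m1)^2) + sum((v[4:6] - m2)^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  res2 <- stain_association(v, g)
  expect_equal(res2$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res2$p_value, pf(f_oracle, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)

  set.seed(13)
  shifted <- c(rnorm(40), rnorm(40, 2))
  expect_lt(stain_association(shifted, rep(g[c(1, 4)], each = 40))$p_value,
            1e-6)
  expect_error(stain_association(1:3, c("a", "a", "b")), ">= 2")
})

test_that("pseudotime regression finds monotone genes and nothing else", {
  pt <- pt_default()
  co <- cohort_default()
  expr <- log2p1(co$tpm)

  # a gene equal to pseudotime regresses with slope 1 and tiny p
  probe <- matrix(rep(pt$samples$pseudotime, 2), nrow = 2, byrow = TRUE,
                  dimnames = list(c("probe1", "probe2"),
                                  pt$samples$sample_id))
  probe["probe2", ] <- 5   # constant gene
  reg0 <- gene_pseudotime_regression(probe, pt)
  expect_equal(reg0$slope[reg0$gene_id == "probe1"], 1, tolerance = 1e-10)
  expect_lt(reg0$p[reg0$gene_id == "probe1"], 1e-12)
  expect_equal(reg0$p[reg0$gene_id == "probe2"], 1)

  reg <- gene_pseudotime_regression(expr, pt)
  prog <- reg$gene_id %in% co$truth$genes$gene_id[co$truth$genes$program]
  # monotone program genes are recovered at raw significance and the
  # genome-wide discoveries are almost exclusively program genes
  expect_gte(mean(reg$p[prog] < 0.05), 0.6)
  expect_gte(mean(prog[reg$q < 0.05]), 0.9)
  expect_gt(median(reg$slope[prog]), 0)

  # permuted pseudotime destroys the signal
  set.seed(14)
  perm <- pt
  perm$samples$pseudotime <- sample(perm$samples$pseudotime)
  regp <- gene_pseudotime_regression(expr[1:2000, ], perm)
  expect_lte(mean(regp$p < 0.05), 0.07)
})

test_that("cluster-vs-rest regression is the pooled-variance t-test", {
  pt <- pt_default()
  co <- cohort_default()
  target <- names(which.max(table(pt$samples$cluster)))
  set.seed(15)
  expr <- matrix(rnorm(20 * nrow(pt$samples)), nrow = 20,
                 dimnames = list(paste0("g", 1:20),
                                 pt$samples$sample_id))
  reg <- cluster_vs_rest_regression(expr, pt, target)
  memb <- pt$samples$cluster == target
  for (g in rownames(expr)[1:5]) {
    tt <- t.test(expr[g, memb], expr[g, !memb], var.equal = TRUE)
    expect_equal(reg$p[reg$gene_id == g], tt$p.value, tolerance = 1e-10)
  }
  const <- expr; const["g1", ] <- 3
  expect_equal(cluster_vs_rest_regression(const, pt, target)$p[1], 1)
  expect_error(cluster_vs_rest_regression(expr, pt, "no-such-cluster"),
               "non-empty")
})

test_that("the ordering is robust to leaving one sample out", {
  lf <- line_expr(n = 12, p = 30, noise = 0.005, seed = 16)
  marker <- setNames(lf$pos, colnames(lf$expr))
  rob <- loo_robustness(lf$expr, marker, seed = 1)
  expect_equal(nrow(rob), 12)
  expect_true(all(rob$spearman_abs > 0.95))

  tiny <- loo_robustness(lf$expr[, 1:4], marker[1:4], seed = 1)
  expect_equal(nrow(tiny), 4)
  expect_error(loo_robustness(lf$expr[, 1:3], marker[1:3]), "at least 4")
})

test_that("leave-one-out orderings of a synthetic cohort stay concordant", {
  co <- cohort_default()
  de <- de_default()
  genes <- supervised_gene_filter(de, 0.01)
  expr <- log2p1(co$tpm[genes, ])
  stain <- setNames(co$metadata$stain, co$metadata$sample_id)
  pt <- pt_default()
  marker <- colMeans(log2p1(co$tpm[pt$root_markers, , drop = FALSE]))
  rob <- loo_robustness(expr, marker, stain = stain, seed = 1)
  expect_gte(mean(rob$spearman_abs), 0.8)
})
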