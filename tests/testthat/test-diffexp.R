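test_that("size factors recover known scalings on a hand fixture", {
  base <- c(10, 20, 5, 8, 40)
  m <- cbind(s1 = base, s2 = 2 * base)
  rownames(m) <- paste0("g", 1:5)
  sf <- size_factors(m)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  ident <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(ident) <- paste0("g", 1:5)
  expect_equal(unname(size_factors(ident)), rep(1, 3), tolerance = 1e-12)
})

test_that("size factors fall back to total counts for fully zero-inflated data", {
  m <- matrix(c(4, 0, 0, 0, 5, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_warning(sf <- size_factors(m), "total-count")
  cs <- colSums(m)
  expect_equal(unname(sf), unname(cs / exp(mean(log(cs)))),
               tolerance = 1e-12)
})

test_that("moment dispersion estimates recover the simulation truth", {
  set.seed(41)
  n <- 40
  groups <- rep(c("A", "B"), each = n / 2)
  mu <- rlnorm(2000, 3, 1)
  pois <- matrix(rpois(2000 * n, mu), nrow = 2000,
                 dimnames = list(paste0("g", 1:2000), paste0("s", 1:n)))
  expect_lte(estimate_dispersion(pois, groups)$common, 0.05)

  nb <- matrix(rnbinom(2000 * n, mu = mu, size = 1 / 0.3), nrow = 2000,
               dimnames = dimnames(pois))
  est <- estimate_dispersion(nb, groups)
  expect_equal(est$common, 0.3, tolerance = 0.1)

  # a flat gene carries no information and takes the common value
  nb["g1", ] <- 0
  est2 <- estimate_dispersion(nb, groups)
  expect_equal(unname(est2$gene["g1"]), est2$common)
})

test_that("the exact test reduces to the binomial test in the Poisson limit", {
  set.seed(42)
  for (i in 1:50) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    y1 <- rpois(nA, 5); y2 <- rpois(nB, 5)
    expect_equal(
      nb_exact_test(y1, y2, 0),
      binom.test(sum(y1), sum(y1) + sum(y2), nA / (nA + nB))$p.value,
      tolerance = 1e-10
    )
  }
})

test_that("the exact test agrees with brute-force conditional enumeration", {
  set.seed(43)
  for (i in 1:50) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    phi <- 0.5
    S <- sample(1:50, 1); s1 <- sample(0:S, 1)
    y1 <- c(s1, rep(0, nA - 1)); y2 <- c(S - s1, rep(0, nB - 1))
    # oracle: joint NB probabilities at an arbitrary common mean,
    # renormalized over all splits of S
    w <- dnbinom(0:S, size = nA / phi, mu = 3 * nA) *
      dnbinom(S:0, size = nB / phi, mu = 3 * nB)
    w <- w / sum(w)
    p_oracle <- sum(w[w <= w[s1 + 1] * (1 + 1e-7)])
    expect_equal(nb_exact_test(y1, y2, phi), p_oracle, tolerance = 1e-10)
    expect_equal(nb_exact_test(y2, y1, phi), nb_exact_test(y1, y2, phi),
                 tolerance = 1e-12)
  }
  expect_equal(nb_exact_test(c(0, 0), c(0, 0, 0), 0.3), 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("differential expression recovers the activation program", {
  co <- cohort_default()
  de <- de_default()
  prog <- de$gene_id %in% co$truth$genes$gene_id[co$truth$genes$program]
  expect_gte(mean(de$q[prog] < 0.05), 0.8)
  expect_lte(mean(de$q[!prog] < 0.05), 0.07)
  # the program rises with activation (log_fc is FOS_POS over FOS_NEG)
  expect_gt(mean(de$log_fc[prog & de$q < 0.05] > 0), 0.95)
})

test_that("permuted labels yield near-uniform p-values", {
  co <- cohort_default()
  set.seed(7)
  meta <- co$metadata
  meta$stain <- sample(meta$stain)
  de <- run_de(co$counts[1:2000, ], meta)
  expect_lte(mean(de$p < 0.05), 0.07)
})

test_that("identical groups produce no signal at all", {
  set.seed(9)
  base <- matrix(rnbinom(200 * 3, mu = 20, size = 3), nrow = 200)
  counts <- cbind(base, base)
  dimnames(counts) <- list(paste0("g", 1:200), paste0("s", 1:6))
  meta <- sample_metadata(colnames(counts),
                          stain = rep(c("FOS_POS", "FOS_NEG"), each = 3))
  de <- run_de(counts, meta)
  expect_equal(de$p, rep(1, 200), tolerance = 1e-6)
})

test_that("exact-test p-values track an independent edgeR analysis", {
  set.seed(10)
  n <- 20
  mu <- rlnorm(300, 3, 1)
  fc <- ifelse(seq_len(300) <= 60, 3, 1)
  counts <- cbind(
    matrix(rnbinom(300 * n / 2, mu = mu, size = 1 / 0.2), ncol = n / 2),
    matrix(rnbinom(300 * n / 2, mu = mu * fc, size = 1 / 0.2),
           ncol = n / 2)
  )
  dimnames(counts) <- list(paste0("g", 1:300), paste0("s", 1:n))
  meta <- sample_metadata(colnames(counts),
                          stain = rep(c("FOS_NEG", "FOS_POS"),
                                      each = n / 2))
  de <- run_de(counts, meta)

  y <- edgeR::DGEList(counts,
                      group = rep(c("N", "P"), each = n / 2))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)$table
  p_edger <- et[de$gene_id, "PValue"]
  expect_gt(cor(-log10(pmax(de$p, 1e-300)),
                -log10(pmax(p_edger, 1e-300)),
                method = "spearman"), 0.9)
})
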