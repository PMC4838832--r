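# Shared fixtures. Heavy objects (a default cohort and its DE table) are
# built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

cohort_default <- function(seed = 1) {
  cached(paste0("cohort_", seed), simulate_cohort(sim_config(seed = seed)))
}

de_default <- function(seed = 1) {
  cached(paste0("de_", seed), {
    co <- cohort_default(seed)
    run_de(co$counts, co$metadata,
           exclude = co$truth$samples$relabelled)
  })
}

pt_default <- function(seed = 1) {
  cached(paste0("pt_", seed), {
    co <- cohort_default(seed)
    order_pseudotime(co$tpm, de_default(seed), co$metadata, seed = seed)
  })
}

# tiny 3-gene x 2-sample TPM fixture
tiny_tpm <- function() {
  m <- matrix(c(0, 1, 7, 2.5, 0, 100), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

# samples spread along a 1-D continuum in gene space, plus tiny noise
line_expr <- function(n = 40, p = 50, noise = 0.01, seed = 7) {
  set.seed(seed)
  pos <- sort(runif(n))
  # loadings bounded away from zero so no gene degenerates to pure noise
  loadings <- sample(c(-1, 1), p, replace = TRUE) * runif(p, 0.5, 2)
  m <- outer(loadings, pos) + matrix(rnorm(p * n, 0, noise), p, n)
  dimnames(m) <- list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n))
  list(expr = m, pos = pos)
}
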