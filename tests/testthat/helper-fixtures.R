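# Shared fixtures and independent oracles for the test suite.

# Reduced-scale simulation for unit tests (full defaults are exercised in
# the acceptance suite).
small_sim <- function(seed, n_samples = 60,
                      cell_types = c(alpha = 80, beta = 80, gamma = 80),
                      n_markers = 20, n_multifunctional = 15,
                      n_background_genes = 150, ...) {
  simulate_bulk(n_samples = n_samples, cell_types = cell_types,
                n_markers = n_markers, n_multifunctional = n_multifunctional,
                n_background_genes = n_background_genes, seed = seed, ...)
}

small_net <- function(expr, min_module_size = 30, ...) {
  suppressWarnings(build_network(expr, min_module_size = min_module_size, ...))
}

# Bare network object built from an assignment alone (enrichment and
# classification only need the assignment / provenance fields).
fake_network <- function(assignment, provenance = "primary") {
  structure(list(soft_power = 6L, assignment = assignment, eigengenes = NULL,
                 membership = NULL, provenance = provenance,
                 params = list()),
            class = "coexpression_network")
}

# Random genes x samples matrix with dimnames.
rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# --- independent oracles -------------------------------------------------

# Upper hypergeometric tail by direct summation of binomial coefficients.
hyper_tail_oracle <- function(ov, n_module, n_marker, n_background) {
  ks <- ov:min(n_module, n_marker)
  if (ov == 0) return(1)
  sum(choose(n_marker, ks) * choose(n_background - n_marker, n_module - ks)) /
    choose(n_background, n_module)
}

# Standard unsigned TOM by explicit triple loop.
tom_oracle <- function(expr, power) {
  C <- abs(cor(t(expr)))^power
  n <- nrow(C)
  A <- C; diag(A) <- 0
  k <- rowSums(A)
  out <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      out[i, j] <- out[j, i] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  dimnames(out) <- dimnames(C)
  out
}

# OLS residuals by the normal equations, one gene at a time.
ols_residual_oracle <- function(expr, design) {
  t(apply(expr, 1, function(y) {
    beta <- solve(t(design) %*% design, t(design) %*% y)
    y - as.vector(design %*% beta)
  }))
}

# Adjusted Rand index by pair counting.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
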