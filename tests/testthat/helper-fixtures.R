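# Shared fixtures: small configurations and brute-force oracles used
# across test files. Everything is generated in code at test time.

quick_config <- function(seed = 1L, n_genes = 200, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

# Brute-force TOM by triple loop; independent of the matrix implementation.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# Brute-force one-way ANOVA from raw sums of squares.
anova_bruteforce <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Random valid adjacency matrix (symmetric, [0,1], unit diagonal).
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Expression matrix with two planted correlated blocks on a noise
# background: within-block correlation rho, between-block factor
# correlation exactly zero (factors orthogonalized in sample).
planted_block_expr <- function(n_per_block = 50, n_noise = 0, n_samples = 30,
                               rho = 0.9, seed = 1) {
  set.seed(seed)
  lambda <- sqrt(rho / (1 - rho))
  q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_samples * 2), n_samples, 2))))
  f <- q[, 2:3] * sqrt(n_samples - 1)   # centered, unit-sd, orthogonal factors
  make_block <- function(n, fac) {
    matrix(lambda * fac, n, n_samples, byrow = TRUE) +
      matrix(stats::rnorm(n * n_samples), n, n_samples)
  }
  expr <- rbind(make_block(n_per_block, f[, 1]),
                make_block(n_per_block, f[, 2]),
                matrix(stats::rnorm(n_noise * n_samples), n_noise, n_samples))
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  expr
}
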