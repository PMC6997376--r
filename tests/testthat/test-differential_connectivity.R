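make_conn_expr <- function(r_target, n_genes, n_samples = 16, seed = 1) {
  set.seed(seed)
  lambda <- sqrt(r_target / (1 - r_target))
  f <- rnorm(n_samples)
  expr <- t(sapply(seq_len(n_genes), function(i) lambda * f + rnorm(n_samples)))
  rownames(expr) <- paste0("g", seq_len(n_genes))
  expr
}

test_that("kWithin matches hand arithmetic on exact-correlation fixtures", {
  # two genes, perfect within-group correlation
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  mods <- c(g1 = 1L, g2 = 1L)
  k <- group_connectivity(expr, mods, beta = 12)
  expect_equal(k$kwithin, c(1, 1))

  # three genes with pairwise r = 0.9 exactly: kWithin = 2 * 0.9^12
  r <- matrix(0.9, 3, 3); diag(r) <- 1
  ch <- chol(r)
  base <- matrix(rnorm(3 * 200), 3, 200)
  base <- t(scale(t(base))); base <- base - rowMeans(base)
  # orthonormalize rows, then impose the exact correlation structure
  q <- qr.Q(qr(t(base)))[, 1:3]
  expr3 <- t(q %*% ch)
  rownames(expr3) <- paste0("g", 1:3)
  k3 <- group_connectivity(expr3, c(g1 = 1L, g2 = 1L, g3 = 1L), beta = 12)
  expect_equal(k3$kwithin, rep(2 * 0.9^12, 3), tolerance = 1e-10)
  expect_equal(2 * 0.9^12, 0.564859, tolerance = 1e-6)

  # orthogonal centered genes: kWithin = 0
  m0 <- scale(matrix(rnorm(40), 20, 2), center = TRUE, scale = FALSE)
  expr0 <- t(qr.Q(qr(m0)))
  rownames(expr0) <- c("g1", "g2")
  k0 <- group_connectivity(expr0, c(g1 = 1L, g2 = 1L), beta = 12)
  expect_equal(k0$kwithin, c(0, 0), tolerance = 1e-20)
})

test_that("kWithin respects its bounds on random inputs", {
  set.seed(21)
  expr <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(paste0("g", 1:30), NULL))
  mods <- stats::setNames(rep(c(1L, 2L, 0L), each = 10), rownames(expr))
  k <- group_connectivity(expr, mods, beta = 12)
  expect_equal(nrow(k), 20)              # module 0 excluded
  expect_true(all(k$kwithin >= 0))
  expect_true(all(k$kwithin <= 9))       # module size - 1
  expect_error(group_connectivity(expr[, 1:2], mods), ">= 3 samples")
})

test_that("module ANOVA matches hand computation and degenerate contracts", {
  tbl <- data.frame(gene_id = rep(c("a", "b"), 2), module = 1L,
                    group = factor(rep(c("g1", "g2"), each = 2)),
                    kwithin = c(1, 2, 3, 4))
  res <- module_connectivity_anova(tbl)
  expect_equal(res$f, 8)                 # SSB = 4, SSW = 1, df (1, 2)
  expect_equal(res$p, stats::pf(8, 1, 2, lower.tail = FALSE))

  same <- data.frame(gene_id = rep(c("a", "b", "c"), 3), module = 1L,
                     group = factor(rep(c("g1", "g2", "g3"), each = 3)),
                     kwithin = rep(c(0.1, 0.2, 0.3), 3))
  r2 <- module_connectivity_anova(same)
  expect_equal(r2$f, 0)
  expect_equal(r2$p, 1)

  sep <- data.frame(gene_id = rep(c("a", "b"), 2), module = 1L,
                    group = factor(rep(c("g1", "g2"), each = 2)),
                    kwithin = c(1, 1, 2, 2))
  r3 <- module_connectivity_anova(sep)
  expect_true(r3$degenerate)
  expect_equal(r3$p, 0)
})

test_that("module ANOVA F matches a brute-force sum-of-squares oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n_genes <- sample(5:10, 1)
    k <- abs(rnorm(3 * n_genes))
    tbl <- data.frame(gene_id = rep(paste0("g", 1:n_genes), 3), module = 1L,
                      group = factor(rep(c("c", "l", "h"), each = n_genes)),
                      kwithin = k)
    res <- module_connectivity_anova(tbl)
    oracle <- anova_bruteforce(k, rep(c("c", "l", "h"), each = n_genes))
    expect_lt(abs(res$f - oracle$f), 1e-10)
    expect_lt(abs(res$p - oracle$p), 1e-10)
  }
})

test_that("a planted connectivity-gain module is flagged with ordered means", {
  hits <- 0; monotone <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_genes = 150, seed = 5000 + r,
      module_specs = list(module_spec(50, rho = c(control = 0.1, low = 0.4,
                                                  high = 0.8))))
    ds <- simulate_dataset(cfg)
    f <- filter_low_expression(ds$counts)
    expr <- log2_normalize(f, median_of_ratios_size_factors(f))
    mods <- build_network_modules(expr)
    planted <- intersect(ds$truth$module_genes[[1]], names(mods))
    lab <- as.integer(names(which.max(table(mods[planted]))))
    if (lab == 0) next
    conn <- connectivity_table(expr, ds$design, mods)
    an <- module_connectivity_anova(conn)
    row <- an[an$module == lab, ]
    if (row$significant) hits <- hits + 1
    if (row$mean_control < row$mean_low && row$mean_low < row$mean_high) {
      monotone <- monotone + 1
    }
  }
  expect_gte(hits, n_rep - 1)
  expect_gte(monotone, n_rep - 1)
})

test_that("Bonferroni thresholds reproduce the printed values", {
  expect_equal(attr(bonferroni_threshold(34), "signif3"), 1.47e-3)
  expect_equal(attr(bonferroni_threshold(18), "signif3"), 2.78e-3)
  expect_equal(attr(bonferroni_threshold(1497), "signif3"), 3.34e-5)
  expect_equal(as.numeric(bonferroni_threshold(1)), 0.05)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("no-effect simulations rarely pass the Bonferroni threshold", {
  # gene-level kWithin values within a module are correlated, so the raw
  # per-module p is anti-conservative; the assertion follows the procedure
  # as run (Bonferroni alpha/M over the tested modules).
  design <- simulate_design(sim_config(n_genes = 10, seed = 1))
  n_rep <- 50
  sig <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    expr <- matrix(rnorm(100 * 48), 100, 48,
                   dimnames = list(paste0("g", 1:100), design$sample_id))
    mods <- stats::setNames(rep(1:4, each = 25L), rownames(expr))
    conn <- connectivity_table(expr, design, mods)
    an <- module_connectivity_anova(conn)
    sig <- sig + sum(an$significant)
    total <- total + nrow(an)
  }
  expect_lte(sig / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})
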