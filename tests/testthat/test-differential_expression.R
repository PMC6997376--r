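# Fixture: a balanced 3-group design matching the analysed study layout.
make_design <- function(n_per_group = 16, groups = c("control", "low", "high")) {
  simulate_design(sim_config(n_genes = 10, n_per_group = n_per_group,
                             groups = groups, seed = 1))
}

test_that("dispersion estimator recovers Poisson and NB truths", {
  design <- make_design()
  cells <- interaction(design$exposure, design$sex, design$week, drop = TRUE)
  n_rep <- 500
  set.seed(101)
  pois <- matrix(rpois(n_rep * 48, 100), n_rep, 48)
  a_pois <- estimate_dispersion(pois, cells)
  expect_gte(mean(a_pois < 0.02), 0.9)

  set.seed(102)
  nb <- matrix(rnbinom(n_rep * 48, mu = 100, size = 2), n_rep, 48)
  a_nb <- estimate_dispersion(nb, cells)
  expect_gt(median(a_nb), 0.3)
  expect_lt(median(a_nb), 0.7)

  const <- matrix(5L, 3, 48)
  expect_equal(as.numeric(estimate_dispersion(const, cells)), rep(1e-8, 3))
})

test_that("NB IRLS matches the Poisson closed form and caps degenerate fits", {
  set.seed(3)
  y <- rpois(30, 40)
  X <- matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_nb_glm(y, X, dispersion = 0)
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-8)
  expect_true(fit$converged)

  fit0 <- fit_nb_glm(rep(0L, 30), X, dispersion = 0.1)
  expect_true(all(fit0$fitted < 1e-8))
  expect_true(is.finite(fit0$loglik))
})

test_that("NB IRLS recovers a planted high-dose coefficient", {
  design <- make_design()
  X <- de_model_matrix(design)
  offset <- rep(0, 48)
  high <- design$exposure == "high"
  est <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    mu <- ifelse(high, 400, 200)
    y <- rnbinom(48, mu = mu, size = 10)
    fit_nb_glm(y, X, dispersion = 0.1, offset = offset)$coefficients[["exposurehigh"]]
  }, 0)
  expect_lt(abs(median(est) - log(2)), 0.15)
})

test_that("LRT is invariant to exposure dummy recoding", {
  cfg <- quick_config(seed = 51, n_genes = 30)
  ds <- simulate_dataset(cfg)
  f <- filter_low_expression(ds$counts)
  r1 <- lrt_exposure(f, ds$design, handle_outliers = FALSE)
  d2 <- ds$design
  d2$exposure <- stats::relevel(d2$exposure, "high")
  r2 <- lrt_exposure(f, d2, handle_outliers = FALSE)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-6)
})

test_that("permuting exposure labels leaves the p distribution uniform", {
  cfg <- quick_config(seed = 52, n_genes = 300)
  ds <- simulate_dataset(cfg)
  f <- filter_low_expression(ds$counts)
  set.seed(99)
  d2 <- ds$design
  d2$exposure <- sample(d2$exposure)
  res <- lrt_exposure(f, d2, handle_outliers = FALSE)
  ks <- stats::ks.test(res$pvalue[!is.na(res$pvalue)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a pure sex effect does not inflate the exposure LRT", {
  design <- make_design()
  X_sex <- as.numeric(design$sex == "M")
  set.seed(61)
  counts <- t(vapply(1:300, function(g) {
    mu <- 150 * 2^(0.8 * X_sex)
    rnbinom(48, mu = mu, size = 1 / 0.05)
  }, numeric(48)))
  rownames(counts) <- paste0("g", 1:300)
  colnames(counts) <- design$sample_id
  res <- lrt_exposure(counts, design, handle_outliers = FALSE)
  expect_gt(median(res$pvalue, na.rm = TRUE), 0.4)
  expect_lt(median(res$pvalue, na.rm = TRUE), 0.6)
})

test_that("NB LRT agrees with a Poisson GLM oracle when dispersion vanishes", {
  design <- make_design()
  set.seed(71)
  counts <- matrix(rpois(100 * 48, 120), 100, 48,
                   dimnames = list(paste0("g", 1:100), design$sample_id))
  disp <- stats::setNames(rep(0, 100), rownames(counts))
  res <- lrt_exposure(counts, design, size_factors = rep(1, 48),
                      dispersion = disp, handle_outliers = FALSE,
                      reference = "chisq")
  oracle <- apply(counts, 1, function(y) {
    full <- stats::glm(y ~ exposure + sex + week, data = design,
                       family = stats::poisson())
    red <- stats::glm(y ~ sex + week, data = design, family = stats::poisson())
    stats::pchisq(red$deviance - full$deviance, df = 2, lower.tail = FALSE)
  })
  expect_gte(mean(abs(res$pvalue - oracle) < 0.01), 0.95)
})

test_that("opposite-direction dose patterns are recovered with correct signs", {
  cfg <- sim_config(n_genes = 120, seed = 81,
                    de_specs = list(de_spec(40, -0.8, 0.4)))
  ds <- simulate_dataset(cfg)
  f <- filter_low_expression(ds$counts)
  res <- lrt_exposure(f, ds$design)
  de <- res[res$gene_id %in% ds$truth$de_genes$gene_id, ]
  ok <- de$log2fc_low < 0 & de$log2fc_high > 0
  expect_gte(mean(ok), 0.9)
})

test_that("Wald contrast handles nulls, shifts and the degenerate zero case", {
  cfg <- sim_config(n_genes = 60, groups = c("water", "control"),
                    n_per_group = 16, seed = 91,
                    de_specs = list(de_spec(20, 1, 1)))
  design <- simulate_design(cfg)
  sim <- simulate_counts(design, cfg)
  res <- wald_control_contrast(sim$counts, design)
  de_ids <- sim$truth$de_genes$gene_id
  expect_gt(median(abs(res$z[res$gene_id %in% de_ids])),
            median(abs(res$z[!res$gene_id %in% de_ids])))

  flat <- matrix(50L, 2, 32, dimnames = list(c("g1", "g2"), design$sample_id))
  rflat <- wald_control_contrast(flat, design, size_factors = rep(1, 32),
                                 handle_outliers = FALSE)
  expect_equal(rflat$pvalue, c(1, 1))
})

test_that("Cook's handling flags a spiked count and replaces by trimmed mean", {
  design <- make_design()
  set.seed(111)
  y <- rpois(48, 100)
  y[7] <- 100 * 100
  counts <- matrix(y, 1, dimnames = list("g1", design$sample_id))
  s <- rep(1, 48)
  X <- de_model_matrix(design)
  fit <- fit_nb_glm(y, X, dispersion = 0.05, offset = log(s))
  oh <- cooks_outlier_handle(counts, list(fit), s)
  expect_true(oh$flags[1, 7])
  expect_equal(oh$counts[1, 7],
               round(mean(y, trim = 0.2) * s[7]), ignore_attr = TRUE)

  clean <- matrix(rpois(48, 100), 1, dimnames = list("g1", design$sample_id))
  fitc <- fit_nb_glm(clean[1, ], X, dispersion = 0.05, offset = log(s))
  ohc <- cooks_outlier_handle(clean, list(fitc), s)
  expect_false(any(ohc$flags))
  expect_identical(ohc$counts, clean)
})

test_that("BH adjustment matches the hand-computed step-up and handles NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_fdr(c(0.5, 2)), "\\[0,1\\]")
})

test_that("q-value ordering is monotone in p", {
  set.seed(5)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_identical(order(p), order(q, p))
})
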