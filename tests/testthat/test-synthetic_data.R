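test_that("design has the emulated study layout and is deterministic", {
  cfg <- quick_config(seed = 5)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 48)
  expect_true(all(table(d$exposure) == 16))
  expect_true(all(table(d$exposure, d$sex) == 8))
  expect_true(all(table(d$exposure, d$week) == 8))
  # two tanks of four fish per group and week
  expect_true(all(table(d$tank) == 4))
  expect_identical(d, simulate_design(cfg))

  tiny <- sim_config(n_genes = 10, n_per_group = 1, seed = 1)
  expect_equal(nrow(simulate_design(tiny)), 3)
  expect_error(sim_config(n_genes = 10, n_per_group = 0), "positive")
})

test_that("null simulation has equal group means within Monte-Carlo error", {
  cfg <- quick_config(seed = 21, n_genes = 200)
  ds <- simulate_dataset(cfg)
  expr <- log2(ds$counts + 1)
  ctrl <- ds$design$sample_id[ds$design$exposure == "control"]
  high <- ds$design$sample_id[ds$design$exposure == "high"]
  pvals <- apply(expr, 1, function(x) stats::t.test(x[ctrl], x[high])$p.value)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("planted module correlation dominates the control group", {
  wins <- vapply(1:20, function(r) {
    cfg <- sim_config(
      n_genes = 60, seed = 300 + r, baseline_log2_mean_sd = 1,
      module_specs = list(module_spec(30, rho = c(control = 0, low = 0,
                                                  high = 0.8))))
    ds <- simulate_dataset(cfg)
    genes <- ds$truth$module_genes[[1]]
    mean_abs_r <- function(group) {
      cols <- ds$design$sample_id[ds$design$exposure == group]
      r <- stats::cor(t(log2(ds$counts[genes, cols] + 1)))
      mean(abs(r[upper.tri(r)]))
    }
    mean_abs_r("high") > mean_abs_r("control")
  }, TRUE)
  expect_true(all(wins))
})

test_that("planted correlation strength is recovered from the counts", {
  cfg <- sim_config(
    n_genes = 60, seed = 77, baseline_log2_mean_mu = 9,
    baseline_log2_mean_sd = 0.5, dispersion_log_mu = log(0.01),
    module_specs = list(module_spec(50, rho = c(control = 0.6, low = 0.6,
                                                high = 0.6))))
  ds <- simulate_dataset(cfg)
  genes <- ds$truth$module_genes[[1]]
  cols <- ds$design$sample_id[ds$design$exposure == "control"]
  r <- stats::cor(t(log2(ds$counts[genes, cols] + 1)))
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.6), 0.05)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(n_genes = 1000, n_per_group = 1, seed = 9,
                    baseline_log2_mean_mu = log2(150),
                    baseline_log2_mean_sd = 0,
                    dispersion_log_mu = -Inf, dispersion_log_sd = 0,
                    size_factor_log_sd = 0)
  ds <- simulate_counts(simulate_design(cfg), cfg)
  draws <- as.numeric(ds$counts)      # 1000 genes x 3 samples, common mean
  ratio <- stats::var(draws) / mean(draws)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("ground truth is complete and every DE gene has a nonzero shift", {
  cfg <- quick_config(seed = 2, de_specs = list(de_spec(15, 1, 2),
                                                de_spec(10, -0.8, 0.4)),
                      module_specs = list(module_spec(20, rho = c(
                        control = 0.3, low = 0.3, high = 0.3))))
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  expect_equal(nrow(tr$de_genes), 25)
  expect_true(all(abs(tr$de_genes$log2fc_low) + abs(tr$de_genes$log2fc_high) > 0))
  expect_setequal(tr$module_genes[[1]],
                  names(tr$module_assignment)[tr$module_assignment == 1])
  expect_length(tr$size_factors, 48)
  expect_length(tr$dispersion, 200)
  # planted DE and module genes are disjoint unless overlap is flagged
  expect_length(intersect(tr$de_genes$gene_id, tr$module_genes[[1]]), 0)
})

test_that("gene metadata respects bias, planting and degenerate settings", {
  cfg <- sim_config(n_genes = 10000, seed = 13,
                    de_specs = list(de_spec(500, 1, 1)))
  ds <- simulate_dataset(cfg)
  de_flag <- names(ds$lengths) %in% ds$truth$de_genes$gene_id
  expect_lt(abs(stats::cor(ds$lengths, de_flag)), 0.05)

  one <- sim_config(n_genes = 50, seed = 1, n_categories = 1,
                    category_size_range = c(10, 10))
  meta <- simulate_gene_metadata(one)
  expect_length(meta$categories, 1)
  expect_length(meta$categories[[1]], 10)
  expect_error(
    simulate_gene_metadata(sim_config(n_genes = 50, seed = 1,
                                      category_size_range = c(1, 5))),
    ">= 2")
})

test_that("behaviour draws conserve counts and honour degenerate probabilities", {
  cfg <- quick_config(seed = 4, n_genes = 10)
  design <- simulate_design(cfg)
  zp <- matrix(c(0, 0, 1), nrow = 3, ncol = 3, byrow = TRUE,
               dimnames = list(levels(design$exposure),
                               c("bottom", "middle", "top")))
  beh <- simulate_behaviour(design, zp, seed = 8)
  expect_true(all(beh$top == 30))
  expect_true(all(beh$bottom == 0 & beh$middle == 0))
  expect_true(all(beh$bottom + beh$middle + beh$top == 30))
  expect_equal(nrow(beh), 48 * 9)
  expect_identical(beh, simulate_behaviour(design, zp, seed = 8))
  bad <- zp; bad[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(simulate_behaviour(design, bad, seed = 1), "sum to 1")
  bad2 <- zp; bad2[1, ] <- c(-0.5, 0.5, 1)
  expect_error(simulate_behaviour(design, bad2, seed = 1), "\\[0,1\\]")
})

test_that("fish metrics are positive, reproducible and reject bad scales", {
  cfg <- quick_config(seed = 6, n_genes = 10)
  design <- simulate_design(cfg)
  fm <- simulate_fish_metrics(design, seed = 3)
  expect_true(all(fm$weight_g > 0 & fm$fork_length_cm > 0 &
                    fm$liver_mg > 0 & fm$brain_mg > 0))
  expect_identical(fm, simulate_fish_metrics(design, seed = 3))
  expect_error(simulate_fish_metrics(design, sds = c(weight_g = -1,
                                                     fork_length_cm = 0.2,
                                                     liver_mg = 3,
                                                     brain_mg = 1)),
               "positive")
})

test_that("identical config and seed reproduce the whole dataset", {
  cfg <- quick_config(seed = 31, n_genes = 50,
                      de_specs = list(de_spec(5, 1, 1)))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$fish_metrics, b$fish_metrics)
})
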