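test_that("annotation filtering enforces the inclusive 10-gene boundary", {
  universe <- paste0("g", 1:100)
  ann <- list(nine = paste0("g", 1:9),
              ten = paste0("g", 1:10),
              padded = c(paste0("g", 1:9), "not_in_universe", "g10"),
              big = paste0("g", 50:80))
  out <- filter_annotation(ann, universe, min_term_size = 10)
  expect_setequal(names(out), c("ten", "padded", "big"))
  expect_setequal(out$padded, paste0("g", 1:10))
  expect_error(filter_annotation(ann, character(0)), "empty")
})

test_that("annotation filtering matches manual enumeration on a toy set", {
  universe <- paste0("g", 1:30)
  set.seed(9)
  ann <- lapply(1:5, function(i) sample(paste0("g", 1:40), sample(5:20, 1)))
  names(ann) <- paste0("T", 1:5)
  out <- filter_annotation(ann, universe, min_term_size = 8)
  manual <- names(ann)[vapply(ann, function(g)
    length(unique(intersect(g, universe))) >= 8, TRUE)]
  expect_setequal(names(out), manual)
})

test_that("PWF is flat when membership ignores length, monotone when it does not", {
  set.seed(41)
  n <- 10000
  len <- rlnorm(n, log(2000), 0.7)
  mem <- runif(n) < 0.1
  pwf <- fit_pwf(mem, len)
  expect_lt(max(abs(pwf$weights - mean(mem))), 0.02)
  expect_equal(sum(pwf$weights), sum(mem), tolerance = 1e-6)

  p_len <- 0.02 + 0.16 * (rank(len) / n)      # probability grows with length
  mem2 <- runif(n) < p_len
  pwf2 <- fit_pwf(mem2, len)
  w_sorted <- pwf2$weights[order(len)]
  expect_true(all(diff(w_sorted) >= -1e-12))
  expect_gt(mean(w_sorted[(n - 999):n]), mean(w_sorted[1:1000]))

  flat <- fit_pwf(c(TRUE, FALSE, TRUE, FALSE), rep(5, 4))
  expect_true(flat$flat)
  expect_equal(unname(flat$weights), rep(0.5, 4))
  expect_error(fit_pwf(rep(TRUE, 4), 1:4), "non-member")
})

test_that("Wallenius pmf sums to one and reduces exactly to the hypergeometric", {
  for (w in c(0.3, 1, 2.5)) {
    pmf <- wallenius_pmf(30, 170, 40, w)
    expect_lt(abs(sum(pmf) - 1), 1e-8)
  }
  # central case against the closed form on a 50-gene universe
  pmf1 <- wallenius_pmf(15, 35, 20, 1)
  expect_lt(max(abs(pmf1 - stats::dhyper(0:20, 15, 35, 20))), 1e-10)
  expect_error(wallenius_pmf(5, 5, 20, 1), "universe")
  expect_error(wallenius_pmf(5, 5, 4, 0), "> 0")
})

test_that("term test honours degenerate contracts and overlap monotonicity", {
  universe <- paste0("g", 1:60)
  pwf <- rep(0.2, 60)
  term <- universe[1:15]
  expect_equal(wallenius_term_test(term, character(0), universe, pwf), 1)
  # module = universe: every term's overlap is forced, p = 1
  expect_equal(wallenius_term_test(term, universe, universe, pwf), 1)

  # p decreases as observed overlap grows, all else fixed
  p_at <- vapply(3:10, function(x) {
    module <- c(term[1:x], setdiff(universe, term)[1:(20 - x)])
    wallenius_term_test(term, module, universe, pwf)
  }, 0)
  expect_true(all(diff(p_at) < 0))
})

test_that("Wallenius approximation agrees with the weighted sampling oracle", {
  set.seed(17)
  universe <- paste0("g", 1:200)
  len <- stats::setNames(rlnorm(200, log(1500), 0.6), universe)
  module <- sample(universe, 30)
  pwf <- fit_pwf(universe %in% module, len)
  # fixture with odds about 2: long-biased term
  term <- universe[order(len)][121:170]
  p_w <- wallenius_term_test(term, module, universe, pwf)
  p_mc <- sampling_null_test(term, module, universe, pwf,
                             n_draws = 20000, seed = 23)
  expect_lt(abs(p_w - p_mc), 0.02)
  # reproducibility of the sampling null
  expect_identical(p_mc, sampling_null_test(term, module, universe, pwf,
                                            n_draws = 20000, seed = 23))
  expect_warning(sampling_null_test(term, module, universe, pwf,
                                    n_draws = 50, seed = 1), "100 draws")
})

test_that("flat-PWF sampling null matches the hypergeometric", {
  universe <- paste0("g", 1:80)
  pwf <- rep(0.3, 80)
  term <- universe[1:20]
  module <- universe[c(1:8, 30:41)]
  p_mc <- sampling_null_test(term, module, universe, pwf,
                             n_draws = 20000, seed = 3)
  p_hyper <- stats::phyper(8 - 1, 20, 60, 20, lower.tail = FALSE)
  expect_lt(abs(p_mc - p_hyper), 0.02)
})

test_that("a planted category equal to a module's gene set wins the family", {
  cfg <- sim_config(n_genes = 2000, seed = 19, n_categories = 30,
                    category_size_range = c(20, 80),
                    module_specs = list(module_spec(50, rho = c(
                      control = 0.5, low = 0.5, high = 0.5))))
  ds <- simulate_dataset(cfg, planted_modules = 1)
  universe <- ds$truth$gene_ids
  module_genes <- list(m1 = ds$truth$module_genes[[1]])
  enr <- module_enrichment(module_genes, ds$categories, ds$lengths,
                           universe = universe)
  planted_p <- enr$p[enr$term == "MODULE1_SET"]
  expect_equal(planted_p, min(enr$p))
  expect_lt(planted_p, attr(enr, "bonferroni"))
})

test_that("enrichment family size and threshold follow the tested modules", {
  universe <- paste0("g", 1:100)
  lengths <- stats::setNames(rep(1000, 100), universe)
  ann <- list(A = universe[1:20], B = universe[21:40], C = universe[41:60])
  enr <- module_enrichment(list(m = universe[1:15]), ann, lengths)
  # only terms annotating genes of a tested module enter the family
  expect_equal(attr(enr, "n_terms"), 1L)
  expect_equal(as.numeric(attr(enr, "bonferroni")), 0.05)
  empty <- module_enrichment(list(), ann, lengths)
  expect_equal(nrow(empty), 0)
})
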