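#' Simulation configuration
#'
#' Defines the study design and generative parameters emulated by the
#' synthetic-data module: three analysed exposure groups (vehicle control,
#' low and high dose) of 16 fish each (8 male / 8 female, split over two
#' experimental weeks, two tanks per group and week), ~thousands of
#' detectable genes with lognormal baseline expression and dispersion,
#' planted differentially expressed genes (additive and opposite-direction
#' dose patterns), planted co-expression modules whose within-group
#' correlation strength varies by dose, lognormal gene lengths, random
#' category annotations, and multinomial tank-zone counts.
#'
#' @param n_genes Number of simulated genes.
#' @param groups Ordered exposure labels; the first is the vehicle control.
#' @param n_per_group Fish per exposure group (16 in the emulated design).
#' @param sex_balance Fraction of males per group.
#' @param n_weeks Number of experimental weeks the design is split over.
#' @param include_water Add a water control group (used only by the
#'   control-vs-vehicle Wald contrast; excluded from DE/network analyses).
#' @param baseline_log2_mean_mu,baseline_log2_mean_sd Normal parameters of
#'   per-gene baseline log2 mean expression.
#' @param dispersion_log_mu,dispersion_log_sd Lognormal parameters of the
#'   per-gene NB dispersion alpha (variance = m + alpha m^2).
#' @param size_factor_log_sd Lognormal sd of per-sample size factors
#'   (geometric mean forced to 1).
#' @param module_specs List of [module_spec()] planted co-expression modules.
#' @param de_specs List of [de_spec()] planted DE gene groups.
#' @param de_in_modules Allow planted DE genes to overlap module genes.
#' @param length_bias Exponent biasing DE/module membership probability by
#'   gene length (0 = unbiased; positive favours long genes).
#' @param length_log_mu,length_log_sd Lognormal parameters of gene length (bp).
#' @param n_categories Number of annotation categories to simulate.
#' @param category_size_range Length-2 integer range of category sizes.
#' @param zone_probs Matrix (groups x 3, columns bottom/middle/top) of
#'   tank-zone probabilities; defaults encode a dose-dependent shift toward
#'   the top zone.
#' @param seed Integer master seed; each component uses a documented offset
#'   substream (design +0, counts +1, gene metadata +2, behaviour +3,
#'   fish metrics +4) so stages can be regenerated independently.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       groups = c("control", "low", "high"),
                       n_per_group = 16,
                       sex_balance = 0.5,
                       n_weeks = 2,
                       include_water = FALSE,
                       baseline_log2_mean_mu = 7,
                       baseline_log2_mean_sd = 2,
                       dispersion_log_mu = log(0.05),
                       dispersion_log_sd = 0.5,
                       size_factor_log_sd = 0.15,
                       module_specs = list(),
                       de_specs = list(),
                       de_in_modules = FALSE,
                       length_bias = 0,
                       length_log_mu = log(2000),
                       length_log_sd = 0.7,
                       n_categories = 50,
                       category_size_range = c(10, 100),
                       zone_probs = NULL,
                       seed = 1L) {
  stopifnot(length(groups) >= 2, !anyDuplicated(groups))
  if (n_genes <= 0 || n_per_group <= 0 || n_weeks <= 0) {
    stop("n_genes, n_per_group and n_weeks must be positive")
  }
  if (baseline_log2_mean_sd < 0 || dispersion_log_sd < 0 ||
      size_factor_log_sd < 0 || length_log_sd < 0) {
    stop("standard deviation parameters must be >= 0")
  }
  if (sex_balance < 0 || sex_balance > 1) stop("sex_balance must be in [0,1]")
  if (n_categories >= 1 && category_size_range[1] < 2) {
    stop("category_size_range lower bound must be >= 2")
  }
  for (ms in module_specs) {
    if (!inherits(ms, "module_spec")) stop("module_specs must be module_spec objects")
    missing_g <- setdiff(groups, names(ms$lambda))
    if (length(missing_g)) {
      stop("module_spec lacks loadings for group(s): ",
           paste(missing_g, collapse = ", "))
    }
  }
  for (ds in de_specs) {
    if (!inherits(ds, "de_spec")) stop("de_specs must be de_spec objects")
  }
  n_module <- sum(vapply(module_specs, function(m) m$size, 0))
  n_de <- sum(vapply(de_specs, function(d) d$n_genes, 0))
  need <- if (de_in_modules) max(n_module, n_de) else n_module + n_de
  if (need > n_genes) stop("planted modules/DE genes exceed n_genes")
  if (is.null(zone_probs)) {
    zone_probs <- default_zone_probs(groups)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), groups = groups,
    n_per_group = as.integer(n_per_group), sex_balance = sex_balance,
    n_weeks = as.integer(n_weeks), include_water = include_water,
    baseline_log2_mean_mu = baseline_log2_mean_mu,
    baseline_log2_mean_sd = baseline_log2_mean_sd,
    dispersion_log_mu = dispersion_log_mu,
    dispersion_log_sd = dispersion_log_sd,
    size_factor_log_sd = size_factor_log_sd,
    module_specs = module_specs, de_specs = de_specs,
    de_in_modules = de_in_modules, length_bias = length_bias,
    length_log_mu = length_log_mu, length_log_sd = length_log_sd,
    n_categories = as.integer(n_categories),
    category_size_range = as.integer(category_size_range),
    zone_probs = zone_probs, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

default_zone_probs <- function(groups) {
  # dose-dependent shift toward the top zone; water behaves like the vehicle
  base <- rbind(control = c(0.50, 0.35, 0.15),
                low     = c(0.35, 0.35, 0.30),
                high    = c(0.10, 0.25, 0.65))
  zp <- base[pmin(seq_along(groups), nrow(base)), , drop = FALSE]
  rownames(zp) <- groups
  colnames(zp) <- c("bottom", "middle", "top")
  zp
}

#' Planted co-expression module specification
#'
#' Module members share, within each sample, a standard-normal latent factor
#' scaled by a per-group loading `lambda`, plus gene-specific residual noise
#' with sd `sigma`, both on the log2 scale. The expected within-group pairwise
#' correlation of the log2 signal is `rho = lambda^2 / (lambda^2 + sigma^2)`.
#'
#' @param size Number of genes in the module (>= 2; the emulated design uses
#'   >= 20, the minimum detectable module size).
#' @param rho Named vector of target within-group correlations in `[0, 1)`,
#'   one per exposure group (alternative to `lambda`).
#' @param lambda Named vector of per-group factor loadings (>= 0).
#' @param sigma Residual log2 sd (> 0).
#' @return A list of class `module_spec` with per-group `lambda` and `sigma`.
#' @export
module_spec <- function(size, rho = NULL, lambda = NULL, sigma = 0.5) {
  if (size < 2) stop("module size must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(lambda)) {
    if (is.null(rho)) stop("provide rho or lambda")
    if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
    lambda <- sigma * sqrt(rho / (1 - rho))
    names(lambda) <- names(rho)
  }
  if (any(lambda < 0)) stop("lambda must be >= 0")
  structure(list(size = as.integer(size), lambda = lambda, sigma = sigma),
            class = "module_spec")
}

#' Planted differential-expression specification
#'
#' A block of genes sharing the same log2 fold changes of the low and high
#' dose groups relative to the control; opposite signs encode
#' opposite-direction dose patterns.
#'
#' @param n_genes Number of genes in the block.
#' @param log2fc_low,log2fc_high Log2 fold change of the low/high group vs
#'   control.
#' @return A list of class `de_spec`.
#' @export
de_spec <- function(n_genes, log2fc_low, log2fc_high) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 log2fc_low = log2fc_low, log2fc_high = log2fc_high),
            class = "de_spec")
}

#' Simulate the sample design
#'
#' Deterministic balanced layout: `n_per_group` fish per exposure group,
#' sexes in the configured proportion, weeks balanced within group and sex,
#' and two tanks per group and week (four fish each in the default design).
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `sample_id`, `fish_id`, `exposure`
#'   (factor, control level first), `sex`, `week`, `tank`.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$groups
  if (config$include_water) groups <- c("water", groups)
  n <- config$n_per_group
  rows <- list()
  for (g in groups) {
    n_male <- round(n * config$sex_balance)
    sex <- rep(c("M", "F"), c(n_male, n - n_male))
    # weeks alternate within each sex so both factors stay balanced
    week <- unlist(lapply(c(n_male, n - n_male), function(k)
      rep_len(seq_len(config$n_weeks), k)))
    idx <- order(week, sex)
    sex <- sex[idx]; week <- week[idx]
    tank <- integer(n)
    for (w in unique(week)) {
      iw <- which(week == w)
      tank[iw] <- (seq_along(iw) - 1L) %/% 4L + 1L
    }
    rows[[g]] <- data.frame(
      exposure = g, sex = sex, week = week,
      tank = paste0(g, "_w", week, "_t", tank),
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$fish_id <- sprintf("fish%03d", seq_len(nrow(design)))
  design$sample_id <- sprintf("S%03d", seq_len(nrow(design)))
  design$exposure <- factor(design$exposure, levels = groups)
  design$sex <- factor(design$sex, levels = c("F", "M"))
  design$week <- factor(design$week)
  rownames(design) <- design$sample_id
  design[, c("sample_id", "fish_id", "exposure", "sex", "week", "tank")]
}

#' Simulate the count matrix with ground truth
#'
#' Counts are negative-binomial draws with mean
#' `s_j * 2^(b_g + Delta_g(group_j) + lambda_{g,group_j} f_{m(g),j} + eps_gj)`
#' where `s_j` is the sample size factor, `b_g` the baseline log2 mean,
#' `Delta_g` the planted DE log2 shift, `f_{m,j}` a standard-normal module
#' factor shared by module members within a sample, and `eps_gj` the module
#' residual noise; the per-gene dispersion is lognormal. The water group, if
#' present, carries no DE or module signal. Means are capped at 1e8 with a
#' warning. Genes with dispersion below 1e-12 are drawn as Poisson.
#'
#' @param design Output of [simulate_design()].
#' @param config The matching [sim_config()].
#' @param gene_lengths Optional per-gene lengths used to length-bias the
#'   selection of DE/module genes when `config$length_bias != 0`.
#' @return List with `counts` (integer matrix genes x samples) and `truth`,
#'   a complete record of every simulated effect: per-gene baseline,
#'   dispersion and DE shifts, module membership with per-group loadings,
#'   per-sample size factors and the zone probabilities.
#' @export
simulate_counts <- function(design, config, gene_lengths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ng <- config$n_genes
  ns <- nrow(design)
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  b <- stats::rnorm(ng, config$baseline_log2_mean_mu, config$baseline_log2_mean_sd)
  alpha <- exp(stats::rnorm(ng, config$dispersion_log_mu, config$dispersion_log_sd))
  if (config$dispersion_log_mu == -Inf) alpha[] <- 0
  s <- exp(stats::rnorm(ns, 0, config$size_factor_log_sd))
  s <- s / exp(mean(log(s)))
  names(s) <- design$sample_id

  # choose planted gene sets (optionally length-biased, to exercise the PWF)
  w_sel <- rep(1, ng)
  if (config$length_bias != 0) {
    if (is.null(gene_lengths)) {
      stop("length_bias != 0 requires gene_lengths")
    }
    w_sel <- as.numeric(gene_lengths)^config$length_bias
  }
  pool <- seq_len(ng)
  draw_genes <- function(k) {
    if (k > length(pool)) stop("planted gene sets exceed n_genes")
    idx <- sample(pool, k, prob = w_sel[pool])
    pool <<- setdiff(pool, idx)
    idx
  }
  module_of <- integer(ng)
  lambda_mat <- NULL       # modules x groups
  module_genes <- list()
  if (length(config$module_specs)) {
    lambda_mat <- do.call(rbind, lapply(config$module_specs, function(m)
      m$lambda[config$groups]))
    colnames(lambda_mat) <- config$groups
    for (m in seq_along(config$module_specs)) {
      idx <- draw_genes(config$module_specs[[m]]$size)
      module_of[idx] <- m
      module_genes[[m]] <- gene_ids[idx]
    }
  }
  if (config$de_in_modules) pool <- seq_len(ng)
  d_low <- d_high <- numeric(ng)
  de_idx <- integer(0)
  for (ds in config$de_specs) {
    idx <- draw_genes(ds$n_genes)
    d_low[idx] <- ds$log2fc_low
    d_high[idx] <- ds$log2fc_high
    de_idx <- c(de_idx, idx)
  }

  grp <- as.character(design$exposure)
  delta <- matrix(0, ng, ns)
  delta[, grp == config$groups[2]] <- d_low
  if (length(config$groups) >= 3) delta[, grp == config$groups[3]] <- d_high

  log2mu <- b + delta
  if (length(module_genes)) {
    f <- matrix(stats::rnorm(length(module_genes) * ns), length(module_genes), ns)
    # standardize each module factor within every exposure group so the
    # planted within-group correlation is realized, not just expected
    for (g in unique(grp)) {
      cols <- grp == g
      if (sum(cols) >= 2) {
        fg <- f[, cols, drop = FALSE]
        f[, cols] <- (fg - rowMeans(fg)) /
          apply(fg, 1, stats::sd)
      }
    }
    for (m in seq_along(module_genes)) {
      idx <- which(module_of == m)
      lam <- numeric(ns)
      in_grp <- grp %in% colnames(lambda_mat)
      lam[in_grp] <- lambda_mat[m, grp[in_grp]]
      sig <- config$module_specs[[m]]$sigma
      eps <- matrix(stats::rnorm(length(idx) * ns, 0, sig), length(idx), ns)
      log2mu[idx, ] <- log2mu[idx, ] +
        rep(lam * f[m, ], each = length(idx)) + eps
    }
  }
  mu <- sweep(2^log2mu, 2, s, "*")
  if (any(mu > 1e8)) {
    warning("capping ", sum(mu > 1e8), " extreme simulated means at 1e8")
    mu[mu > 1e8] <- 1e8
  }
  counts <- matrix(0L, ng, ns, dimnames = list(gene_ids, design$sample_id))
  pois <- alpha < 1e-12
  if (any(pois)) {
    counts[pois, ] <- stats::rpois(sum(pois) * ns, mu[pois, , drop = FALSE])
  }
  if (any(!pois)) {
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * ns,
                                      mu = mu[!pois, , drop = FALSE],
                                      size = rep(1 / alpha[!pois], ns))
  }

  truth <- list(
    gene_ids = gene_ids,
    baseline_log2_mean = stats::setNames(b, gene_ids),
    dispersion = stats::setNames(alpha, gene_ids),
    size_factors = s,
    de_genes = data.frame(gene_id = gene_ids[de_idx],
                          log2fc_low = d_low[de_idx],
                          log2fc_high = d_high[de_idx],
                          stringsAsFactors = FALSE),
    module_assignment = stats::setNames(module_of, gene_ids),
    module_lambda = lambda_mat,
    module_sigma = vapply(config$module_specs, function(m) m$sigma, 0),
    module_genes = module_genes,
    zone_probs = config$zone_probs)
  list(counts = counts, truth = truth)
}

#' Simulate gene lengths and category annotations
#'
#' Lengths are lognormal. Categories draw genes uniformly (or length-biased
#' when `length_bias != 0`) with sizes uniform over `category_size_range`;
#' categories can additionally be planted as the exact gene set of selected
#' modules so that downstream enrichment has a known positive.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth record from [simulate_counts()] (required for
#'   planting).
#' @param planted_modules Integer indices of modules whose gene sets become
#'   extra categories named `MODULE<m>_SET`.
#' @return List with `lengths` (named numeric, bp) and `categories`
#'   (named list term -> gene ids, with a `description` attribute per use in
#'   GMT files).
#' @export
simulate_gene_metadata <- function(config, truth = NULL, planted_modules = integer(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_categories < 1) stop("n_categories must be >= 1")
  if (config$category_size_range[1] < 2) {
    stop("category_size_range lower bound must be >= 2")
  }
  set.seed(config$seed + 2L)
  gene_ids <- if (!is.null(truth)) truth$gene_ids else
    sprintf("gene%05d", seq_len(config$n_genes))
  ng <- length(gene_ids)
  lengths <- stats::setNames(
    round(stats::rlnorm(ng, config$length_log_mu, config$length_log_sd)) + 1,
    gene_ids)
  w <- if (config$length_bias != 0) lengths^config$length_bias else rep(1, ng)
  size_choices <- seq(config$category_size_range[1],
                      min(config$category_size_range[2], ng))
  sizes <- size_choices[sample.int(length(size_choices),
                                   config$n_categories, replace = TRUE)]
  categories <- lapply(sizes, function(k) sample(gene_ids, k, prob = w))
  names(categories) <- sprintf("CAT%04d", seq_len(config$n_categories))
  if (length(planted_modules)) {
    if (is.null(truth)) stop("planting categories requires the truth record")
    for (m in planted_modules) {
      categories[[sprintf("MODULE%d_SET", m)]] <- truth$module_genes[[m]]
    }
  }
  list(lengths = lengths, categories = categories)
}

#' Simulate tank-position behaviour counts
#'
#' For every fish and observation session, a multinomial draw over the three
#' tank zones (bottom, middle, top) with the fish's group-specific zone
#' probabilities; `n_observations` one-minute observations per session.
#' Sessions cycle through the three assessment periods (spawning, feeding,
#' general) over consecutive days.
#'
#' @param design Output of [simulate_design()].
#' @param zone_probs_per_group Matrix (groups x 3) of zone probabilities,
#'   rows summing to 1.
#' @param n_observations Observations per session (30 in the emulated design).
#' @param n_sessions Sessions per fish (9 = 3 periods x 3 days).
#' @param seed Integer seed.
#' @return Data frame: `fish_id`, `tank`, `session_type`, `day`, `bottom`,
#'   `middle`, `top`.
#' @export
simulate_behaviour <- function(design, zone_probs_per_group,
                               n_observations = 30, n_sessions = 9,
                               seed = 1L) {
  zp <- as.matrix(zone_probs_per_group)
  if (any(zp < 0 | zp > 1)) stop("zone probabilities must lie in [0,1]")
  if (any(abs(rowSums(zp) - 1) > 1e-8)) {
    stop("zone probabilities must sum to 1 per group")
  }
  groups <- levels(design$exposure)
  if (is.null(rownames(zp)) || !all(groups %in% rownames(zp))) {
    stop("zone_probs_per_group needs one named row per exposure group")
  }
  set.seed(seed + 3L)
  types <- rep_len(c("spawning", "feeding", "general"), n_sessions)
  day <- stats::ave(seq_len(n_sessions), types, FUN = seq_along)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- zp[as.character(design$exposure[i]), ]
    cnt <- t(stats::rmultinom(n_sessions, n_observations, p))
    out[[i]] <- data.frame(
      fish_id = design$fish_id[i], tank = design$tank[i],
      session_type = types, day = day,
      bottom = cnt[, 1], middle = cnt[, 2], top = cnt[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate fish health metrics
#'
#' Positive normal draws of body weight (g), fork length (cm), liver weight
#' (mg) and brain weight (mg); no group effect unless `group_effects`
#' multipliers are supplied. Defaults approximate adult zebrafish.
#'
#' @param design Output of [simulate_design()].
#' @param seed Integer seed.
#' @param means,sds Named numeric parameters for `weight_g`, `fork_length_cm`,
#'   `liver_mg`, `brain_mg`.
#' @param group_effects Optional named list metric -> named multiplier vector
#'   per exposure group.
#' @return Data frame keyed by `fish_id` with the four raw measures.
#' @export
simulate_fish_metrics <- function(design, seed = 1L,
                                  means = c(weight_g = 0.55, fork_length_cm = 3.5,
                                            liver_mg = 15, brain_mg = 10),
                                  sds = c(weight_g = 0.06, fork_length_cm = 0.25,
                                          liver_mg = 3, brain_mg = 1.5),
                                  group_effects = list()) {
  if (any(means <= 0) || any(sds <= 0)) {
    stop("means and sds must be positive")
  }
  set.seed(seed + 4L)
  n <- nrow(design)
  draw <- function(metric) {
    mult <- rep(1, n)
    if (!is.null(group_effects[[metric]])) {
      mult <- group_effects[[metric]][as.character(design$exposure)]
    }
    x <- stats::rnorm(n, means[[metric]] * mult, sds[[metric]])
    while (any(x <= 0)) {          # redraw the rare non-positive values
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), means[[metric]] * mult[bad], sds[[metric]])
    }
    x
  }
  data.frame(fish_id = design$fish_id,
             weight_g = draw("weight_g"),
             fork_length_cm = draw("fork_length_cm"),
             liver_mg = draw("liver_mg"),
             brain_mg = draw("brain_mg"),
             stringsAsFactors = FALSE)
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper running every generator with the documented seed
#' substreams.
#'
#' @param config A [sim_config()].
#' @param planted_modules Passed to [simulate_gene_metadata()].
#' @return List: `design`, `counts`, `truth`, `lengths`, `categories`,
#'   `behaviour`, `fish_metrics`.
#' @export
simulate_dataset <- function(config, planted_modules = integer(0)) {
  design <- simulate_design(config)
  meta_first <- config$length_bias != 0
  meta0 <- if (meta_first) simulate_gene_metadata(config) else NULL
  sim <- simulate_counts(design, config,
                         gene_lengths = if (meta_first) meta0$lengths)
  meta <- simulate_gene_metadata(config, truth = sim$truth,
                                 planted_modules = planted_modules)
  if (meta_first) meta$lengths <- meta0$lengths
  zp <- config$zone_probs
  if (config$include_water && !"water" %in% rownames(zp)) {
    zp <- rbind(water = zp[1, ], zp)
    rownames(zp)[1] <- "water"
  }
  behaviour <- simulate_behaviour(design, zp, seed = config$seed)
  fish <- simulate_fish_metrics(design, seed = config$seed)
  list(design = design, counts = sim$counts, truth = sim$truth,
       lengths = meta$lengths, categories = meta$categories,
       behaviour = behaviour, fish_metrics = fish)
}
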