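#' Default study-scale simulation configuration
#'
#' The generator defaults used by the end-to-end workflow: the analysed
#' design (three groups of 16 fish plus the optional water control), a few
#' thousand detectable genes, planted DE blocks with additive and
#' opposite-direction dose patterns, and three planted modules -- a
#' connectivity-gain module, a connectivity-loss module and a
#' dose-stable module.
#'
#' @param seed Master seed.
#' @param n_genes Number of simulated genes.
#' @param include_water Include the water control group.
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 1L, n_genes = 2000,
                                 include_water = TRUE) {
  sim_config(
    n_genes = n_genes,
    include_water = include_water,
    module_specs = list(
      module_spec(80, rho = c(control = 0.10, low = 0.30, high = 0.80)),
      module_spec(60, rho = c(control = 0.60, low = 0.30, high = 0.25)),
      module_spec(50, rho = c(control = 0.50, low = 0.50, high = 0.50))),
    de_specs = list(
      de_spec(30, log2fc_low = 0.8, log2fc_high = 1.2),
      de_spec(30, log2fc_low = -0.6, log2fc_high = -1.0),
      de_spec(20, log2fc_low = -0.8, log2fc_high = 0.4)),
    seed = seed)
}

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]; unknown keys are
#' rejected. Can be populated from a YAML file with
#' [read_pipeline_config()].
#'
#' @param outdir Output directory.
#' @param seed Master seed (also seeds the simulation config when one is
#'   not supplied).
#' @param sim A [sim_config()]; defaults to [default_study_config()].
#' @param stages Named logical toggles: simulate, filter, normalize, de,
#'   network, connectivity, enrich, phenotype, behaviour.
#' @param min_count,min_samples Low-expression filter.
#' @param beta Soft-threshold power.
#' @param min_module_size,max_block_size,cut_height,gap_frac Module
#'   detection.
#' @param alpha Family-wise error rate for Bonferroni thresholds.
#' @param fdr_threshold DE significance surface.
#' @param min_term_size Enrichment term filter.
#' @param signed_kwithin Use signed adjacency for connectivity instead of
#'   `|r|^beta`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "results", seed = 1L, sim = NULL,
                            stages = NULL,
                            min_count = 10, min_samples = 16,
                            beta = 12, min_module_size = 20,
                            max_block_size = 5000, cut_height = 0.99,
                            gap_frac = 0.25, alpha = 0.05,
                            fdr_threshold = 0.10, min_term_size = 10,
                            signed_kwithin = FALSE) {
  stage_names <- c("simulate", "filter", "normalize", "de", "network",
                   "connectivity", "enrich", "phenotype", "behaviour")
  st <- stats::setNames(rep(TRUE, length(stage_names)), stage_names)
  if (!is.null(stages)) {
    unknown <- setdiff(names(stages), stage_names)
    if (length(unknown)) {
      stop("unknown stage toggle(s): ", paste(unknown, collapse = ", "))
    }
    st[names(stages)] <- unlist(stages)
  }
  if (is.null(sim)) sim <- default_study_config(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              stages = st, min_count = min_count, min_samples = min_samples,
              beta = beta, min_module_size = min_module_size,
              max_block_size = max_block_size, cut_height = cut_height,
              gap_frac = gap_frac, alpha = alpha,
              fdr_threshold = fdr_threshold, min_term_size = min_term_size,
              signed_kwithin = signed_kwithin)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` key
#' holds [sim_config()] arguments. Unknown keys in either block are
#' rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "sim")
  unknown <- setdiff(names(y), c(allowed, "sim"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_allowed <- names(formals(sim_config))
    unknown <- setdiff(names(y$sim), sim_allowed)
    if (length(unknown)) {
      stop("unknown sim key(s): ", paste(unknown, collapse = ", "))
    }
    sim <- do.call(sim_config, y$sim)
  }
  y$sim <- sim
  do.call(pipeline_config, y[!vapply(y, is.null, TRUE)])
}

pipeline_files <- function(outdir) {
  f <- c(counts = "counts.tsv", design = "design.csv",
         lengths = "gene_lengths.tsv", categories = "categories.gmt",
         behaviour = "behaviour.tsv", fish = "fish_metrics.tsv",
         truth = "truth.json",
         filtered = "filtered_counts.tsv", size_factors = "size_factors.csv",
         expression = "expression.tsv", de_lrt = "de_lrt.tsv",
         de_wald = "de_wald.tsv", modules = "modules.tsv",
         connectivity = "connectivity.tsv", module_anova = "module_anova.tsv",
         enrichment = "enrichment.tsv", health = "health_tests.tsv",
         behaviour_tests = "behaviour_tests.tsv",
         manifest = "manifest.json")
  stats::setNames(file.path(outdir, f), names(f))
}

require_inputs <- function(stage, needs, files, enabled) {
  missing <- needs[!file.exists(files[needs])]
  if (length(missing)) {
    stop("stage '", stage, "' requires outputs of earlier stage(s); missing: ",
         paste(basename(files[missing]), collapse = ", "),
         if (any(!enabled)) " (an upstream stage is disabled)")
  }
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order (simulate, filter, normalize, de,
#' network, connectivity, enrich, phenotype, behaviour), writing each
#' stage's outputs under `config$outdir`. Stage outputs are written to a
#' `.partial` file and renamed on completion; a failing stage aborts with
#' the stage named. A manifest (config hash, seed, per-output MD5
#' checksums, timings) is written atomically at the end and returned.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- pipeline_files(config$outdir)
  st <- config$stages
  manifest <- list(package = "finbrainnet",
                   version = as.character(utils::packageVersion("finbrainnet")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = list())
  dose_design <- function(design) {
    droplevels(design[design$exposure != "water", ])
  }
  run_stage <- function(name, fun) {
    if (!st[[name]]) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    sums <- tools::md5sum(unlist(outputs))
    manifest$stages[[name]] <<- list(
      outputs = as.list(sums),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }
  write_out <- function(writer, obj, path) {
    tmp <- paste0(path, ".partial")
    writer(obj, tmp)
    file.rename(tmp, path)
    path
  }

  run_stage("simulate", function() {
    ds <- simulate_dataset(config$sim)
    lengths_df <- data.frame(gene_id = names(ds$lengths),
                             length_bp = as.numeric(ds$lengths))
    truth_json <- function(obj, path) {
      jsonlite::write_json(serializable_truth(obj), path, auto_unbox = TRUE,
                           digits = NA)
    }
    c(write_out(write_counts_tsv, ds$counts, files["counts"]),
      write_out(write_design_csv, ds$design, files["design"]),
      write_out(write_tsv, lengths_df, files["lengths"]),
      write_out(write_gmt, ds$categories, files["categories"]),
      write_out(write_tsv, ds$behaviour, files["behaviour"]),
      write_out(write_tsv, ds$fish_metrics, files["fish"]),
      write_out(truth_json, ds$truth, files["truth"]))
  })

  run_stage("filter", function() {
    require_inputs("filter", c("counts", "design"), files, st)
    counts <- read_counts_tsv(files[["counts"]])
    design <- read_design_csv(files[["design"]])
    dd <- dose_design(design)
    kept <- filter_low_expression(counts[, dd$sample_id, drop = FALSE],
                                  config$min_count, config$min_samples)
    # the surviving gene list is reused for every downstream analysis,
    # including the water-vs-vehicle contrast
    write_out(write_counts_tsv, counts[rownames(kept), , drop = FALSE],
              files["filtered"])
  })

  run_stage("normalize", function() {
    require_inputs("normalize", c("filtered", "design"), files, st)
    counts <- read_counts_tsv(files[["filtered"]])
    design <- read_design_csv(files[["design"]])
    dd <- dose_design(design)
    sub <- counts[, dd$sample_id, drop = FALSE]
    s <- median_of_ratios_size_factors(sub)
    expr <- log2_normalize(sub, s)
    sf_df <- data.frame(sample_id = names(s), size_factor = as.numeric(s))
    expr_df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    c(write_out(function(o, p) utils::write.csv(o, p, row.names = FALSE),
                sf_df, files["size_factors"]),
      write_out(write_tsv, expr_df, files["expression"]))
  })

  run_stage("de", function() {
    require_inputs("de", c("filtered", "design"), files, st)
    counts <- read_counts_tsv(files[["filtered"]])
    design <- read_design_csv(files[["design"]])
    dd <- dose_design(design)
    lrt <- lrt_exposure(counts[, dd$sample_id, drop = FALSE], dd)
    lrt$significant <- !is.na(lrt$padj) & lrt$padj < config$fdr_threshold
    out <- write_out(write_tsv, lrt, files["de_lrt"])
    if ("water" %in% design$exposure) {
      wd <- droplevels(design[design$exposure %in% c("water", "control"), ])
      wd$exposure <- factor(as.character(wd$exposure),
                            levels = c("water", "control"))
      wald <- wald_control_contrast(counts[, wd$sample_id, drop = FALSE], wd)
      out <- c(out, write_out(write_tsv, wald, files["de_wald"]))
    }
    out
  })

  run_stage("network", function() {
    require_inputs("network", "expression", files, st)
    expr <- read_expression_tsv(files[["expression"]])
    modules <- build_network_modules(
      expr, beta = config$beta, min_module_size = config$min_module_size,
      cut_height = config$cut_height, gap_frac = config$gap_frac,
      max_block_size = config$max_block_size)
    df <- data.frame(gene_id = names(modules), module = as.integer(modules))
    write_out(write_tsv, df, files["modules"])
  })

  run_stage("connectivity", function() {
    require_inputs("connectivity", c("expression", "modules", "design"),
                   files, st)
    expr <- read_expression_tsv(files[["expression"]])
    mods_df <- read_tsv(files[["modules"]], required = c("gene_id", "module"))
    modules <- stats::setNames(mods_df$module, mods_df$gene_id)
    design <- read_design_csv(files[["design"]])
    dd <- dose_design(design)
    conn <- connectivity_table(expr, dd, modules, beta = config$beta,
                               signed = config$signed_kwithin)
    anova <- module_connectivity_anova(conn, alpha = config$alpha)
    c(write_out(write_tsv, conn, files["connectivity"]),
      write_out(write_tsv, anova, files["module_anova"]))
  })

  run_stage("enrich", function() {
    require_inputs("enrich", c("modules", "module_anova", "lengths",
                               "categories"), files, st)
    mods_df <- read_tsv(files[["modules"]], required = c("gene_id", "module"))
    anova <- read_tsv(files[["module_anova"]], required = c("module", "p"))
    lengths_df <- read_tsv(files[["lengths"]], required = c("gene_id", "length_bp"))
    lengths <- stats::setNames(lengths_df$length_bp, lengths_df$gene_id)
    annotation <- read_gmt(files[["categories"]])
    sig_modules <- anova$module[anova$significant]
    module_genes <- lapply(sig_modules, function(m)
      mods_df$gene_id[mods_df$module == m])
    names(module_genes) <- as.character(sig_modules)
    universe <- mods_df$gene_id
    enr <- module_enrichment(module_genes, annotation, lengths,
                             universe = universe, alpha = config$alpha,
                             min_term_size = config$min_term_size)
    write_out(write_tsv, enr, files["enrichment"])
  })

  run_stage("phenotype", function() {
    require_inputs("phenotype", c("fish", "design"), files, st)
    metrics <- derive_health_indices(read_tsv(files[["fish"]]))
    design <- read_design_csv(files[["design"]])
    res <- health_tests(metrics, design)
    write_out(write_tsv, res, files["health"])
  })

  run_stage("behaviour", function() {
    require_inputs("behaviour", c("behaviour", "design"), files, st)
    records <- read_tsv(files[["behaviour"]])
    design <- read_design_csv(files[["design"]])
    res <- behaviour_tests(records, design, alpha = config$alpha)
    write_out(write_tsv, res, files["behaviour_tests"])
  })

  tmp <- paste0(files[["manifest"]], ".partial")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, files[["manifest"]])
  invisible(manifest)
}

read_expression_tsv <- function(path) {
  df <- read_tsv(path, required = "gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

serializable_truth <- function(truth) {
  truth$module_lambda <- if (!is.null(truth$module_lambda))
    as.data.frame(truth$module_lambda)
  truth
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config), tmp)
  unname(tools::md5sum(tmp))
}
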