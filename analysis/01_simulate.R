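#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the exposure design: a water control, a DMSO vehicle control
# ("control") and two clozapine dose groups ("low" = 20 ug/L, "high" =
# 70 ug/L), 16 fish each (8 male / 8 female over two weeks, two tanks per
# group and week). 2000 genes carry three planted co-expression modules
# (connectivity gain, loss, and dose-stable) and three planted DE blocks
# (up-additive, down-additive, opposite-direction), plus gene lengths,
# category annotations, tank-position counts with a dose-dependent shift
# toward the top zone, and fish morphometrics with no group effect.

library(finbrainnet)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_study_config(seed = 20260921L)
ds <- simulate_dataset(cfg, planted_modules = 1)

write_counts_tsv(ds$counts, file.path(outdir, "counts.tsv"))
write_design_csv(ds$design, file.path(outdir, "design.csv"))
write_tsv(data.frame(gene_id = names(ds$lengths),
                     length_bp = as.numeric(ds$lengths)),
          file.path(outdir, "gene_lengths.tsv"))
write_gmt(ds$categories, file.path(outdir, "categories.gmt"))
write_tsv(ds$behaviour, file.path(outdir, "behaviour.tsv"))
write_tsv(ds$fish_metrics, file.path(outdir, "fish_metrics.tsv"))
jsonlite::write_json(
  list(de_genes = ds$truth$de_genes,
       module_sizes = lengths(ds$truth$module_genes),
       module_lambda = as.data.frame(ds$truth$module_lambda)),
  file.path(outdir, "truth_summary.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d genes x %d samples (%s)\n",
            nrow(ds$counts), ncol(ds$counts),
            paste(levels(ds$design$exposure), collapse = "/")))
cat(sprintf("planted: %d DE genes, %d modules (%s genes)\n",
            nrow(ds$truth$de_genes), length(ds$truth$module_genes),
            paste(lengths(ds$truth$module_genes), collapse = "/")))
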