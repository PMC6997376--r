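#!/usr/bin/env Rscript
# Stage 5 — differential intramodular connectivity.
#
# Per exposure group (vehicle, low, high), each module gene's kWithin is
# the sum of |r|^12 to the other module genes, with correlations computed
# within that group's 16 samples only. Per module, a one-way ANOVA of
# gene-level kWithin across groups flags clozapine-associated connectivity
# change at the Bonferroni threshold alpha / n_modules.

library(finbrainnet)

expr_df <- read_tsv("results/data/expression.tsv", required = "gene_id")
expr <- as.matrix(expr_df[, -1])
rownames(expr) <- expr_df$gene_id
mods_df <- read_tsv("results/modules.tsv", required = c("gene_id", "module"))
modules <- stats::setNames(mods_df$module, mods_df$gene_id)
design <- read_design_csv("results/data/design.csv")
dose <- droplevels(design[design$exposure != "water", ])

conn <- connectivity_table(expr, dose, modules, beta = 12)
write_tsv(conn, "results/connectivity.tsv")

an <- module_connectivity_anova(conn, alpha = 0.05)
an <- an[order(-an$n_genes), ]
write_tsv(an, "results/module_connectivity_anova.tsv")

thr <- attr(an, "bonferroni")
cat(sprintf("tested %d modules; Bonferroni threshold %.3g\n", nrow(an),
            signif(thr, 3)))
cat(sprintf("%d modules with significant connectivity change\n",
            sum(an$significant)))
print(an[, c("module", "n_genes", "mean_control", "mean_low", "mean_high",
             "p", "significant")], row.names = FALSE, digits = 3)
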