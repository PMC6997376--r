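#!/usr/bin/env Rscript
# Stage 3 — differential expression.
#
# Per-gene negative-binomial GLM with likelihood-ratio test for exposure
# (full: exposure + sex + week; reduced: sex + week) on the vehicle + dose
# samples, Cook's-distance outlier replacement, BH-FDR at 0.10; and the
# water-vs-vehicle Wald contrast on the same gene list.

library(finbrainnet)

counts <- read_counts_tsv("results/data/filtered_counts.tsv")
design <- read_design_csv("results/data/design.csv")
dose <- droplevels(design[design$exposure != "water", ])

lrt <- lrt_exposure(counts[, dose$sample_id], dose)
lrt$significant <- !is.na(lrt$padj) & lrt$padj < 0.10
write_tsv(lrt[order(lrt$pvalue), ], "results/de_lrt.tsv")

cat(sprintf("exposure LRT: %d genes tested, %d with Cook's outliers replaced\n",
            sum(!is.na(lrt$pvalue)), sum(lrt$n_outliers > 0)))
cat(sprintf("significant at FDR < 0.10: %d genes\n", sum(lrt$significant)))
top <- head(lrt[order(lrt$pvalue),
                c("gene_id", "base_mean", "log2fc_low", "log2fc_high",
                  "pvalue", "padj")], 5)
print(top, row.names = FALSE, digits = 3)

wd <- droplevels(design[design$exposure %in% c("water", "control"), ])
wd$exposure <- factor(as.character(wd$exposure), levels = c("water", "control"))
wald <- wald_control_contrast(counts[, wd$sample_id], wd)
write_tsv(wald[order(wald$pvalue), ], "results/de_wald_water_vs_vehicle.tsv")
cat(sprintf("water-vs-vehicle Wald: %d genes at FDR < 0.10 (vehicle effect)\n",
            sum(wald$padj < 0.10, na.rm = TRUE)))
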