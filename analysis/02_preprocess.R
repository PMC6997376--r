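#!/usr/bin/env Rscript
# Stage 2 — detectability filter and normalization.
#
# Genes are kept when they reach 10 reads in at least 16 samples (the
# exposure-group size) among the vehicle + dose samples; the surviving
# gene list is reused by every later stage, including the water-vs-vehicle
# contrast. Size factors follow the median-of-ratios convention on the
# vehicle + dose samples, and the network stage's expression matrix is
# log2(normalized count + 1).

library(finbrainnet)

counts <- read_counts_tsv("results/data/counts.tsv")
design <- read_design_csv("results/data/design.csv")
dose <- droplevels(design[design$exposure != "water", ])

kept <- filter_low_expression(counts[, dose$sample_id], min_count = 10,
                              min_samples = 16)
cat(sprintf("filter: %d of %d genes retained (>=10 reads in >=16 of %d samples)\n",
            nrow(kept), nrow(counts), nrow(dose)))

write_counts_tsv(counts[rownames(kept), ], "results/data/filtered_counts.tsv")

s <- median_of_ratios_size_factors(kept)
cat(sprintf("size factors: range %.3f - %.3f\n", min(s), max(s)))
utils::write.csv(data.frame(sample_id = names(s), size_factor = as.numeric(s)),
                 "results/data/size_factors.csv", row.names = FALSE)

expr <- log2_normalize(kept, s)
write_tsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
          "results/data/expression.tsv")
cat(sprintf("expression matrix: %d genes x %d samples written\n",
            nrow(expr), ncol(expr)))
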