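#!/usr/bin/env Rscript
# Stage 7 — fish health indices and tank-position behaviour.
#
# Health: condition factor k = 100 w / L^3, hepatosomatic index and
# brain-body ratio (both on body weight net of liver), tested per sex by
# the dose-group ANOVA (exposure + week) and the water-vs-vehicle
# regression. Behaviour: per zone (bottom/middle/top) and assessment
# period (spawning/feeding/general), zone counts out of 30 one-minute
# observations modelled on exposure + sex + week, days as independent
# observations; 18 tests give the Bonferroni threshold 0.05/18.

library(finbrainnet)

design <- read_design_csv("results/data/design.csv")
metrics <- derive_health_indices(read_tsv("results/data/fish_metrics.tsv"))
health <- health_tests(metrics, design)
write_tsv(health, "results/health_tests.tsv")
cat(sprintf("health metrics: %d tests, min p = %.3f (no planted effect)\n",
            nrow(health), min(health$p)))

records <- read_tsv("results/data/behaviour.tsv")
beh <- behaviour_tests(records, design, alpha = 0.05)
write_tsv(beh, "results/behaviour_tests.tsv")
cat(sprintf("behaviour: %d tests, Bonferroni threshold %.3g\n",
            attr(beh, "n_tests"), signif(attr(beh, "bonferroni"), 3)))
anova_rows <- beh[beh$analysis == "anova", ]
cat(sprintf("dose ANOVA significant: %d of %d (dose-dependent zone shift)\n",
            sum(anova_rows$significant), nrow(anova_rows)))
contrast_rows <- beh[beh$analysis == "contrast", ]
cat(sprintf("water-vs-vehicle contrast significant: %d of %d\n",
            sum(contrast_rows$significant), nrow(contrast_rows)))
print(beh[beh$significant, c("zone", "session", "analysis", "p")],
      row.names = FALSE, digits = 3)
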