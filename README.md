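# finbrainnet

Dose-response differential expression and co-expression **network
connectivity** analysis for zebrafish brain RNA-seq, with a fully
ground-truthed synthetic-data generator.

Toxicogenomic exposure studies of this shape compare a vehicle control
against two drug doses (16 fish per group, both sexes, two experimental
weeks) and ask: which genes shift in mean expression with dose; whether
co-expression **modules** change how tightly they are wired
(intramodular connectivity) even when means do not; which functional
categories those modules are enriched for once gene-length bias is
corrected; and whether fish health or tank-position behaviour responds to
dose. `finbrainnet` implements the full workflow for analysts running or
re-analysing such designs, and validates every stage by parameter
recovery on simulated data with known truth.

## The statistics at the core

* **Differential expression** — per-gene negative-binomial GLM
  (log link, median-of-ratios size factors as offsets,
  method-of-moments dispersion), likelihood-ratio test of
  `~ exposure + sex + week` vs `~ sex + week` (df = 2) with a
  small-sample `F(df, df2)` reference, Cook's-distance outlier
  replacement by trimmed means, BH-FDR at 0.10, and a Wald contrast for
  water-vs-vehicle.
* **Signed network** — adjacency `a = ((1 + r)/2)^12`, topological
  overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
  average-linkage clustering of `1 − TOM` with a simplified dynamic cut,
  minimum module size 20, maximum block size 5000.
* **Differential connectivity** — per exposure group,
  `kWithin_i = Σ_{j∈M} |r_ij|^12` from within-group correlations; per
  module a one-way ANOVA of gene-level kWithin across groups, Bonferroni
  at `α/M` (0.05/34 → 1.47E-03 in a 34-module analysis).
* **Enrichment** — probability weighting function (isotonic fit of
  membership vs gene length) feeding a Wallenius noncentral
  hypergeometric over-representation test (exact sequential-draw
  recurrence), Bonferroni over the term family (0.05/1497 → 3.34E-05).
* **Phenotypes** — condition factor `k = 100 w / L³`, HSI and brain-body
  ratio (both on weight net of liver); behaviour zone counts modelled on
  exposure + sex + week, 18 tests → threshold 2.78E-03.

See `vignettes/dose-network-methods.Rmd` for models, assumptions,
parameter defaults and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `07_phenotype_behaviour.R`),
writing tables under `results/`. The simulation plants a
connectivity-gain module (within-group correlation 0.10 → 0.30 → 0.80
across control/low/high), a connectivity-loss module, a dose-stable
module, and 80 DE genes. The connectivity stage prints:

```
tested 6 modules; Bonferroni threshold 0.00833
3 modules with significant connectivity change
 module n_genes mean_control mean_low mean_high        p significant
      1      79      0.01268  0.03526   3.25839 4.98e-57        TRUE
      2      38      0.00654  0.00598   0.00719 9.06e-01       FALSE
      3      32      0.08094  0.19274   0.08628 2.86e-05        TRUE
      4      30      0.00317  0.00189   0.00417 1.29e-01       FALSE
      5      24      0.36450  0.06022   0.02838 3.36e-10        TRUE
      6      20      0.01032  0.00176   0.00448 1.49e-01       FALSE
```

Module 1 is the planted gain module (79/80 genes recovered): its mean
intramodular connectivity climbs 0.013 → 0.035 → 3.26 with dose — the
coordinated tightening of a co-expressed gene set under exposure — and
module 5 is the recovered loss module (0.36 → 0.06 → 0.03). The
enrichment stage then flags the category planted as module 1's gene set
(`p = 8.4e-135`, far below the family threshold), the DE stage reports
86 genes at FDR < 0.10 (80 planted), and the behaviour stage finds the
dose-dependent shift toward the top tank zone in all 9 zone × session
ANOVAs while the water-vs-vehicle contrast stays null — the pattern this
study design is built to detect.

Programmatic use mirrors the scripts:

```r
library(finbrainnet)
ds   <- simulate_dataset(default_study_config(seed = 1))
keep <- filter_low_expression(ds$counts[, 17:64])      # vehicle + doses
expr <- log2_normalize(keep, median_of_ratios_size_factors(keep))
mods <- build_network_modules(expr)                    # beta = 12
conn <- connectivity_table(expr, droplevels(ds$design[17:64, ]), mods)
module_connectivity_anova(conn)
```

`run_pipeline(pipeline_config(outdir = "results"))` runs everything from
one validated configuration and writes a checksummed manifest.

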