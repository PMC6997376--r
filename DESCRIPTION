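Package: finbrainnet
Title: Dose-Response Differential Expression and Co-Expression Network
    Connectivity Analysis for Zebrafish Brain RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a dose-response transcriptomic
    workflow for zebrafish brain RNA-seq: count filtering and median-of-ratios
    normalization, per-gene negative-binomial generalized linear models with
    likelihood-ratio tests for exposure and Cook's-distance outlier handling,
    signed weighted co-expression network construction with topological-overlap
    module detection, per-exposure-group intramodular connectivity with a
    module-level ANOVA for differential connectivity, gene-length-bias-corrected
    category enrichment via the Wallenius noncentral hypergeometric
    distribution, and fish health and tank-position behaviour statistics. A
    synthetic-data generator emulates the three-group (vehicle, low, high dose)
    study design with planted differential expression, planted co-expression
    modules whose correlation strength varies by dose, gene lengths, category
    annotations and multinomial tank-zone counts, so every stage is exercised
    end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
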