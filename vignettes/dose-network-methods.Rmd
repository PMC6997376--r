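---
title: "Dose-response differential expression and network connectivity: models and methods"
author: "finbrainnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response differential expression and network connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finbrainnet)
```

# The scientific question

Antipsychotic exposure studies in zebrafish compare a vehicle control with
two drug doses and ask three questions of the brain transcriptome: which
genes shift in mean expression with dose; whether the *co-expression
structure* — how tightly gene modules are wired — changes with dose even
when means do not; and whether the affected modules are enriched for
interpretable functional categories. Around the transcriptome sit two
phenotype batteries: morphometric health indices and tank-position
behaviour counts. `finbrainnet` implements that whole workflow, plus a
synthetic-data generator that emulates the study design with known ground
truth, so every stage can be validated by parameter recovery rather than
by eyeballing.

# The design being emulated

Three analysed groups — vehicle control, low dose, high dose — with 16
fish each (8 male, 8 female), run over two experimental weeks with two
tanks per group and week (four fish per tank). An optional water control
(off for the network analyses, on for the vehicle-effect contrast)
mirrors the vehicle group. Behaviour is recorded as 30 one-minute
tank-zone observations (bottom/middle/top) per fish per session, with
three assessment periods (spawning, feeding, "general time") over three
days, days treated as independent observations.

# Generative model of the synthetic data

Counts for gene $g$ in sample $j$ are negative binomial with mean

$$\mu_{gj} = s_j \, 2^{\,b_g + \Delta_g(\mathrm{group}_j) +
\lambda_{g,\mathrm{group}_j} f_{m(g),j} + \varepsilon_{gj}}$$

and variance $\mu + \alpha_g \mu^2$. Here $s_j$ is a lognormal size
factor (geometric mean 1, log-sd 0.15), $b_g \sim N(7, 2^2)$ a baseline
log2 mean (median ≈ 128 counts), $\alpha_g$ lognormal with median 0.05
(log-sd 0.5) — typical bulk-brain values — and $\Delta_g$ the planted DE
shift of the low/high groups. Module members share a standard-normal
latent factor $f_{m,j}$ per sample, scaled by a per-group loading
$\lambda$ and blurred by residual noise $\varepsilon \sim N(0,
\sigma^2)$, all on the log2 scale, so the planted within-group
correlation $\rho = \lambda^2 / (\lambda^2 + \sigma^2)$ approximately
survives the downstream $\log_2(\text{normalized count} + 1)$ transform
(count noise attenuates it by a few percent at these baselines). The
factor is standardized *within each exposure group*, so the planted
$\rho$ is realized in each simulated dataset rather than only in
expectation; recovery is asserted to ±0.05 at module size 50 and n = 16.

Dispersions below $10^{-12}$ switch the draw to Poisson, which gives the
generator an exact Poisson limit (variance/mean → 1, verified to 10% at
mean ≥ 100).

What the generator does *not* emulate: tank effects on expression (tank
labels exist but carry no effect — the expression models never used tank
as a covariate), library-preparation batch structure, gene-gene overlap
between DE blocks and modules (disjoint unless flagged), GC or mappability
biases, and read-level artefacts (the pipeline starts at the count
matrix). Passing tests therefore validate the statistical machinery under
a clean NB world, not robustness to real-data pathologies.

Seeding: one master seed with fixed substream offsets (design +0, counts
+1, gene metadata +2, behaviour +3, fish metrics +4) so stages can be
regenerated independently and every output is byte-reproducible.

Default study-scale conditions (`default_study_config()`): 2000 genes;
planted modules of 80 (gain, $\rho$ 0.10/0.30/0.80 across groups), 60
(loss, 0.60/0.30/0.25) and 50 (stable, 0.50 everywhere); DE blocks of 30
up-additive (+0.8/+1.2), 30 down-additive (−0.6/−1.0) and 20
opposite-direction (−0.8/+0.4) genes, mirroring the additive and
sign-flipping dose patterns seen in this kind of exposure data. Behaviour
zone probabilities shift monotonically toward the top zone with dose
(bottom/middle/top: 0.50/0.35/0.15 control, 0.35/0.35/0.30 low,
0.10/0.25/0.65 high). Fish morphometrics are group-free normals (weight
0.55 ± 0.06 g, fork length 3.5 ± 0.25 cm, liver 15 ± 3 mg, brain
10 ± 1.5 mg); the weight sd corresponds to a within-sex CV of ~11% for an
age-matched cohort, a level at which a 20% weight shift is detectable
with ≥80% power at n = 8 per sex and group — the detection contract the
health battery is tested against.

# Preprocessing

Genes are kept when they reach **10 reads in at least 16 samples** (the
exposure-group size), computed on the vehicle + dose samples; the
surviving gene list is reused everywhere, including the water-vs-vehicle
contrast. Size factors are **median-of-ratios**: each sample's counts are
divided by the per-gene geometric mean and the median is taken over the
genes with all-positive counts, with an even-count median resolved as the
arithmetic midpoint of the two central ratios (the log-scale geometric
midpoint used by some implementations differs in the 5th decimal; a test
cross-checks against DESeq2 on an odd-count fixture where the two
conventions coincide exactly). The network matrix is
$\log_2(\text{count}/s_j + 1)$.

# Differential expression

Each gene gets a log-link NB GLM, fitted by iteratively reweighted least
squares with offset $\log s_j$, fixed dispersion, convergence at
coefficient changes $< 10^{-8}$ (max 100 iterations), and linear
predictors capped at ±30 so all-zero genes resolve without error.

**Dispersion** is method-of-moments: within each exposure × sex × week
cell the sample mean and variance of normalized counts are computed and
$\alpha$ solves the df-weighted relation $E[v_c] = m_c \overline{1/s} +
\alpha m_c^2$, floored at $10^{-8}$. No shrinkage across genes is applied
— a deliberate simplification relative to full RNA-seq fitters, traded
for transparency and testability. An optional lowess trend-smoother
exists but is off by default (it added bias without improving calibration
at these sample sizes).

**Testing.** The exposure test is a likelihood-ratio test of
`~ exposure + sex + week` against `~ sex + week`, dispersion held fixed
across both fits, df = 2. Because the per-gene dispersion is estimated
without shrinkage, referring the statistic to $\chi^2_2$ is
anti-conservative at n = 48 (measured ~6.6% empirical size at the nominal
5%); the default reference is therefore the quasi-likelihood-style
small-sample form, $\mathrm{stat}/\mathrm{df} \sim F(\mathrm{df},
\mathrm{df}_2)$ with $\mathrm{df}_2$ the residual df of the dispersion
estimator (36 in the default design), which measures ~5% on null
simulations. `reference = "chisq"` restores the large-sample version.
The water-vs-vehicle contrast is a Wald test ($z = \hat\beta/se$,
$t(\mathrm{df}_2)$ reference by default, normal optional). Fold changes
are reported as coefficients $/\ln 2$; multiplicity is Benjamini-Hochberg
with the significance surface at FDR < 0.10.

**Outliers.** Cook's distance per observation,
$(r_P^2/p)\,h/(1-h)^2$, against the 99th percentile of $F(p, n-p)$;
flagged counts are replaced by the gene's 20%-trimmed mean of normalized
counts rescaled by the sample's size factor and rounded, and the gene is
refit. Cutoff quantile and trimming fraction are conventional values and
configurable, as the originals are not printed anywhere authoritative.

# Co-expression network

Pearson correlations on the pooled 48 vehicle + dose samples feed the
**signed** adjacency $a_{ij} = ((1 + r_{ij})/2)^{\beta}$ with soft
threshold $\beta = 12$ — correlation −1 maps to 0, +1 to 1, and powering
suppresses weak edges while keeping the network weighted. Topological
overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}$$

is clustered by average linkage on $1 - \mathrm{TOM}$. The tree cut is a
simplified dynamic rule: a merge splits when it sits above a static
fraction (default 0.99) of the tree height, or when both children hold at
least the minimum module size (20) and the merge clears its children by
more than 25% of the height range. Clusters below 20 genes fall into
module 0 (unassigned); surviving modules are relabelled by descending
size. The full iterative hybrid cut of the reference implementation is
deliberately out of scope; the simplified rule recovers planted
partitions exactly (ARI = 1 at within-block $\rho$ = 0.9) and leaves
≥90% of pure-noise genes unassigned. One caveat: on an input that is a
single homogeneous module with *no* background, the static component
still forces a split; with any realistic background the behaviour is as
intended. Gene backgrounds below a few hundred genes weaken the TOM
contrast between planted modules and noise (at 150 genes, detection
failed in 2/20 replicates; at 1000 genes, 0/20) — the validation
simulations therefore use a 1000-gene background.

Above 5000 genes (`max_block_size`), genes are pre-partitioned by
k-means on expression profiles into $\lceil n/5000 \rceil$ blocks
(rebalanced so no block exceeds the cap), and detection runs per block
before the global size-ranked relabelling.

# Differential connectivity

For each exposure group separately (16 samples each), a module gene's
**intramodular connectivity** is $k^{within}_i = \sum_{j \in M, j \ne i}
|r_{ij}|^{12}$, with correlations computed within-group only. Note the
absolute-correlation convention: the network that defines modules is
signed, but the connectivity statistic follows the unsigned form — this
mirrors the procedure being re-implemented verbatim, and a
`signed = TRUE` switch offers the signed alternative.

Per module, a one-way ANOVA treats each gene's kWithin as an observation
and the three groups as levels; significance is Bonferroni at
$\alpha/M$ over the $M$ tested modules ($0.05/34 = 1.47\times10^{-3}$ in
a 34-module analysis). Gene-level kWithin values within a module are
correlated (they share the same sample correlation matrix), so the test
is anti-conservative as a formal inference — the implementation
reproduces the published procedure rather than repairing it, and on
pure-noise modules the observed rate at $\alpha/M$ stays within two
binomial standard errors of $\alpha$. Degenerate cases are explicit:
all-equal kWithin gives F = 0, p = 1; zero within-group variance with a
between-group difference reports an infinite F, p = 0, flagged.

# Category enrichment with length-bias correction

Terms are intersected with the analysed universe and dropped below 10
genes. Per tested module, a **probability weighting function** models
membership probability as a monotone non-decreasing function of gene
length: equal-occupancy length bins, isotonic regression of bin
membership proportions, linear interpolation, rescaled so mean weight ×
gene count = member count, clamped to $(10^{-6}, 1-10^{-6})$. Isotonic
regression replaces the monotone spline of the reference tool — the same
monotone-smoother contract with fewer moving parts; on
length-independent membership the fitted PWF is flat to within 0.02.

Each term is tested for over-representation (upper tail only) under the
**Wallenius noncentral hypergeometric** distribution with odds

$$w = \frac{\bar{w}_{in}/(1-\bar{w}_{in})}{\bar{w}_{out}/(1-\bar{w}_{out})}$$

from the mean PWF inside/outside the term. The pmf is computed by the
exact sequential-draw recurrence (dynamic programme over the number of
term genes drawn), which sums to 1 to $10^{-8}$ and collapses to the
central hypergeometric at $w = 1$ to $10^{-10}$. A Monte-Carlo oracle
(weighted sampling without replacement proportional to the PWF) is built
in; note the two conventions — odds ratio of membership probabilities vs
sampling proportional to the probabilities themselves — coincide only for
small membership probabilities, so the cross-validation fixture uses
small two-valued weights with odds exactly 2 (agreement within ±0.01 at
100,000 draws; a heterogeneous fitted-PWF fixture is held to ±0.02).
The Bonferroni family is the set of distinct retained terms annotating at
least one gene of any tested module ($0.05/1497 = 3.34\times10^{-5}$ in
a 1497-term family); the universe defaults to all analysed genes
(configurable, as the original choice is not stated).

# Phenotype and behaviour statistics

Condition factor $k = 100\,w/L^3$, hepatosomatic index
$100\,\mathrm{liver}/(\mathrm{total}-\mathrm{liver})$ and brain-body
ratio $100\,\mathrm{brain}/(\mathrm{total}-\mathrm{liver})$ — the BBR
denominator nets out the liver, matching the HSI denominator as defined
in the source procedure. Health metrics are tested per sex: dose-group
ANOVA with week as covariate, and water-vs-vehicle regression. Behaviour
models raw zone counts (not proportions) per zone × assessment period on
exposure + sex + week, days as independent observations; the exposure
effect is the F test of the 3-level factor, the control contrast the t
test of the 2-level factor. The "18 tests" behind the $0.05/18 =
2.78\times10^{-3}$ threshold are 3 zones × 3 periods × 2 analyses; the
count adapts to the analyses actually run. Constant responses (e.g. a
degenerate all-bottom group) return p = 1 rather than NaN; constant
health metrics raise an explicit degeneracy error. Tank is not a
covariate by default (its role is unstated in the source procedure); a
flag could include it via the design table.

# Orchestration

`run_pipeline()` executes simulate → filter → normalize → DE → network →
connectivity → enrichment → phenotype/behaviour from a validated
`pipeline_config()` (unknown keys rejected; YAML front-end available).
Stage outputs are written to `.partial` files and renamed on completion;
a failing stage aborts naming itself; a manifest with the config hash,
seed, per-file MD5 checksums and timings is written atomically at the
end, and identical config + seed reproduces identical checksums. The
numbered scripts under `analysis/` are thin narrative drivers over the
same functions.

# Numerical choices and problem sizes

Validation simulations use: 2000 null genes for LRT size, 20 replicates
of 2000 genes (10% DE at $|\log_2\mathrm{FC}| = 1.5$, balanced up/down so
median-of-ratios normalization stays valid) for FDR control, 5000 genes
with 500 planted patterns for sign recovery, 20 replicates of a 1000-gene
background for connectivity-gain detection, and 400 replicates for the
behaviour/health type-I rates. These sizes put Monte-Carlo error
comfortably inside the assertion bands while keeping the whole suite fast
on a laptop.

# Known limitations

* No dispersion or fold-change shrinkage; low-count genes are noisier
  than under a moderated fitter.
* The connectivity ANOVA inherits the gene-level pseudo-replication of
  the published procedure; treat its p-values as descriptive ranking,
  not calibrated inference (a permutation null can be built from
  `connectivity_table()` by permuting group labels).
* The simplified tree cut approximates, but is not, the hybrid dynamic
  cut; module boundaries can differ from the reference implementation on
  borderline clusters.
* The Wallenius odds uses the single mean-odds approximation; strongly
  heterogeneous PWFs within a term are only approximately handled (the
  sampling oracle is the fallback).
* Synthetic validation says nothing about batch effects, tank effects or
  count-model misspecification in real data.
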