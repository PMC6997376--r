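#' Build the differential-expression model matrix
#'
#' Dummy-coded design with intercept: exposure (control level first), sex,
#' week, and optionally the exposure-by-sex interaction.
#'
#' @param design Sample design data frame with factors `exposure`, `sex`,
#'   `week`.
#' @param terms Character vector of main effects to include.
#' @param interaction Add `exposure:sex` columns.
#' @return Model matrix, checked for full column rank.
#' @export
de_model_matrix <- function(design, terms = c("exposure", "sex", "week"),
                            interaction = FALSE) {
  rhs <- paste(terms, collapse = " + ")
  if (interaction) rhs <- paste(rhs, "+ exposure:sex")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = design)
  if (qr(X)$rank < ncol(X)) {
    stop("model matrix is not of full column rank on these samples")
  }
  X
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH over the non-missing p-values; `NA`s are excluded from the
#' test count and propagated.
#'
#' @param p Numeric vector of p-values in `[0,1]`, `NA` allowed.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Cook's-distance outlier handling
#'
#' For each gene's fitted full model, Cook's distance per observation is
#' `(pearson_residual^2 / p) * h / (1 - h)^2` with `p` model parameters and
#' leverage `h`. Observations above the 99th percentile of `F(p, n - p)`
#' are flagged and their counts replaced by the gene's trimmed mean of
#' normalized counts, rescaled by the sample's size factor and rounded.
#'
#' @param counts Count matrix (genes matching `fits`).
#' @param fits List of [fit_nb_glm()] results, one per gene.
#' @param size_factors Per-sample size factors.
#' @param cooks_quantile F-distribution quantile for the cutoff.
#' @param trim Trimming fraction for the replacement mean.
#' @return List: `counts` (adjusted matrix), `flags` (logical matrix of
#'   replaced observations).
#' @export
cooks_outlier_handle <- function(counts, fits, size_factors,
                                 cooks_quantile = 0.99, trim = 0.2) {
  counts <- validate_counts(counts, allow_real = TRUE)
  n <- ncol(counts)
  flags <- matrix(FALSE, nrow(counts), n, dimnames = dimnames(counts))
  adjusted <- counts
  for (g in seq_len(nrow(counts))) {
    fit <- fits[[g]]
    p <- length(fit$coefficients)
    cutoff <- stats::qf(cooks_quantile, p, n - p)
    mu <- fit$fitted
    v <- mu * (1 + fit$dispersion * mu)
    r2 <- (counts[g, ] - mu)^2 / pmax(v, 1e-300)
    h <- pmin(fit$leverage, 1 - 1e-8)
    cooks <- (r2 / p) * h / (1 - h)^2
    bad <- cooks > cutoff
    if (any(bad)) {
      flags[g, bad] <- TRUE
      tm <- mean(counts[g, ] / size_factors, trim = trim)
      adjusted[g, bad] <- round(tm * size_factors[bad])
    }
  }
  list(counts = adjusted, flags = flags)
}

#' Likelihood-ratio test for exposure
#'
#' Per-gene NB GLM with log link and log-size-factor offset. The full model
#' is `~ exposure + sex + week` (optionally `+ exposure:sex`), the reduced
#' model drops the exposure terms (for the interaction analysis, the
#' reduced model keeps the main effects and drops only the interaction).
#' The dispersion is estimated once per gene and held fixed across both
#' fits. The statistic is `2 (ll_full - ll_reduced)` with df equal to the
#' number of dropped columns (2 for three exposure levels). By default
#' `stat / df` is referred to an `F(df, df2)` distribution with `df2` the
#' residual df of the dispersion estimator -- the quasi-likelihood-style
#' small-sample reference that keeps the test calibrated when per-gene
#' dispersions are estimated without shrinkage; `reference = "chisq"`
#' gives the large-sample chi-square reference instead. Genes with
#' Cook's-distance outliers have the flagged counts replaced by trimmed
#' means and are refit.
#'
#' @param counts Filtered count matrix (genes x samples).
#' @param design Sample design restricted to the analysed groups.
#' @param size_factors Optional; computed by median-of-ratios when missing.
#' @param dispersion Optional per-gene dispersions; estimated from the
#'   exposure-by-sex-by-week cells when missing.
#' @param handle_outliers Apply Cook's-distance replacement and refit.
#' @param interaction Test the exposure-by-sex interaction instead of the
#'   exposure main effect.
#' @param reference Reference distribution for the statistic (see above).
#' @param df2 Denominator df of the F reference; defaults to the `df`
#'   attribute of the dispersion vector, else `n - ncol(X_full)`.
#' @param cooks_quantile,trim Outlier-handling controls.
#' @return Data frame with one row per gene: `gene_id`, `base_mean` (mean of
#'   normalized counts), `log2fc_low`, `log2fc_high`, `stat`, `pvalue`,
#'   `padj` (BH over converged genes), `n_outliers`, `converged`.
#' @export
lrt_exposure <- function(counts, design, size_factors = NULL,
                         dispersion = NULL, handle_outliers = TRUE,
                         interaction = FALSE, reference = c("f", "chisq"),
                         df2 = NULL, cooks_quantile = 0.99, trim = 0.2) {
  reference <- match.arg(reference)
  counts <- validate_counts(counts)
  design <- droplevels(design)
  if (nrow(design) != ncol(counts)) stop("design rows must match samples")
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(counts)
  offset <- log(size_factors)
  if (is.null(dispersion)) {
    cells <- interaction(design$exposure, design$sex, design$week, drop = TRUE)
    dispersion <- estimate_dispersion(counts, cells, size_factors)
  }
  X_full <- de_model_matrix(design, interaction = interaction)
  if (interaction) {
    X_red <- de_model_matrix(design, interaction = FALSE)
  } else {
    X_red <- de_model_matrix(design, terms = c("sex", "week"))
  }
  df <- ncol(X_full) - ncol(X_red)
  if (is.null(df2)) {
    df2 <- attr(dispersion, "df") %||% (nrow(design) - ncol(X_full))
  }
  exp_levels <- levels(design$exposure)
  lfc_cols <- paste0("exposure", exp_levels[-1])

  ng <- nrow(counts)
  z <- sweep(counts, 2, size_factors, "/")
  res <- data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(ng)),
    base_mean = rowMeans(z),
    log2fc_low = NA_real_, log2fc_high = NA_real_,
    stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
    n_outliers = 0L, converged = FALSE, stringsAsFactors = FALSE)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    a <- dispersion[g]
    fit_f <- fit_nb_glm(y, X_full, a, offset)
    if (handle_outliers) {
      oh <- cooks_outlier_handle(matrix(y, 1), list(fit_f), size_factors,
                                 cooks_quantile, trim)
      if (any(oh$flags)) {
        y <- oh$counts[1, ]
        res$n_outliers[g] <- sum(oh$flags)
        fit_f <- fit_nb_glm(y, X_full, a, offset)
      }
    }
    fit_r <- fit_nb_glm(y, X_red, a, offset)
    res$converged[g] <- fit_f$converged && fit_r$converged
    cf <- fit_f$coefficients
    if (length(lfc_cols) >= 1 && lfc_cols[1] %in% names(cf)) {
      res$log2fc_low[g] <- cf[[lfc_cols[1]]] / log(2)
    }
    if (length(lfc_cols) >= 2 && lfc_cols[2] %in% names(cf)) {
      res$log2fc_high[g] <- cf[[lfc_cols[2]]] / log(2)
    }
    if (res$converged[g]) {
      res$stat[g] <- max(0, 2 * (fit_f$loglik - fit_r$loglik))
      res$pvalue[g] <- if (reference == "f") {
        stats::pf(res$stat[g] / df, df, df2, lower.tail = FALSE)
      } else {
        stats::pchisq(res$stat[g], df = df, lower.tail = FALSE)
      }
    }
  }
  res$padj <- bh_fdr(res$pvalue)
  attr(res, "df") <- df
  res
}

#' Wald test for a two-level control contrast
#'
#' Per-gene NB GLM on a two-level exposure factor (e.g. water vs vehicle)
#' with sex and week covariates; `z = beta / se(beta)` for the exposure
#' coefficient, two-sided p-value (by default from a t distribution with
#' the dispersion-estimator's residual df, the small-sample analogue of
#' the normal reference; `reference = "normal"` for the large-sample
#' version), BH adjustment.
#'
#' @inheritParams lrt_exposure
#' @param reference `"t"` (small-sample default) or `"normal"`.
#' @return Data frame: `gene_id`, `base_mean`, `log2fc`, `z`, `pvalue`,
#'   `padj`, `n_outliers`, `converged`.
#' @export
wald_control_contrast <- function(counts, design, size_factors = NULL,
                                  dispersion = NULL, handle_outliers = TRUE,
                                  reference = c("t", "normal"), df2 = NULL,
                                  cooks_quantile = 0.99, trim = 0.2) {
  reference <- match.arg(reference)
  counts <- validate_counts(counts)
  design <- droplevels(design)
  if (nlevels(design$exposure) != 2) {
    stop("the control contrast requires exactly two exposure levels")
  }
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(counts)
  offset <- log(size_factors)
  if (is.null(dispersion)) {
    cells <- interaction(design$exposure, design$sex, design$week, drop = TRUE)
    dispersion <- estimate_dispersion(counts, cells, size_factors)
  }
  X <- de_model_matrix(design)
  if (is.null(df2)) {
    df2 <- attr(dispersion, "df") %||% (nrow(design) - ncol(X))
  }
  coef_name <- paste0("exposure", levels(design$exposure)[2])
  z_mat <- sweep(counts, 2, size_factors, "/")
  ng <- nrow(counts)
  res <- data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(ng)),
    base_mean = rowMeans(z_mat),
    log2fc = NA_real_, z = NA_real_, pvalue = NA_real_, padj = NA_real_,
    n_outliers = 0L, converged = FALSE, stringsAsFactors = FALSE)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    fit <- fit_nb_glm(y, X, dispersion[g], offset)
    if (handle_outliers) {
      oh <- cooks_outlier_handle(matrix(y, 1), list(fit), size_factors,
                                 cooks_quantile, trim)
      if (any(oh$flags)) {
        y <- oh$counts[1, ]
        res$n_outliers[g] <- sum(oh$flags)
        fit <- fit_nb_glm(y, X, dispersion[g], offset)
      }
    }
    res$converged[g] <- fit$converged
    b <- fit$coefficients[[coef_name]]
    se <- fit$se[[coef_name]]
    res$log2fc[g] <- b / log(2)
    if (res$converged[g] && is.finite(se) && se > 0) {
      res$z[g] <- b / se
      res$pvalue[g] <- if (reference == "t") {
        2 * stats::pt(-abs(res$z[g]), df = df2)
      } else {
        2 * stats::pnorm(-abs(res$z[g]))
      }
    } else if (res$converged[g] && b == 0) {
      res$z[g] <- 0; res$pvalue[g] <- 1
    }
  }
  res$padj <- bh_fdr(res$pvalue)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
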