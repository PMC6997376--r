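#' Per-group intramodular connectivity
#'
#' For each gene in a module, kWithin is the sum over the other module
#' genes of the absolute within-group correlation raised to the power
#' `beta` (`|r|^beta`); correlations are computed from the given group's
#' samples only. A signed variant (`((1+r)/2)^beta`) is available.
#'
#' @param expr_group Expression matrix restricted to one group's samples
#'   (>= 3).
#' @param modules Named integer vector gene -> module label (0 ignored).
#' @param beta Soft-threshold power.
#' @param signed Use the signed adjacency instead of `|r|^beta`.
#' @return Data frame: `gene_id`, `module`, `kwithin`.
#' @export
group_connectivity <- function(expr_group, modules, beta = 12, signed = FALSE) {
  if (ncol(expr_group) < 3) stop("need >= 3 samples in the group")
  ids <- rownames(expr_group)
  if (is.null(ids)) stop("expression matrix needs gene ids")
  if (is.null(names(modules))) stop("module assignment needs gene ids")
  mods <- sort(unique(modules[modules > 0]))
  out <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    genes <- names(modules)[modules == mods[i]]
    missing <- setdiff(genes, ids)
    if (length(missing)) stop("module genes absent from expression matrix")
    r <- gene_correlation(expr_group[genes, , drop = FALSE])
    a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
    diag(a) <- 0
    out[[i]] <- data.frame(gene_id = genes, module = mods[i],
                           kwithin = rowSums(a), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Connectivity table across exposure groups
#'
#' Runs [group_connectivity()] separately for each exposure group of the
#' design and stacks the results.
#'
#' @param expr Full expression matrix (genes x samples).
#' @param design Sample design (`sample_id`, `exposure`).
#' @param modules Named module assignment.
#' @param beta,signed Passed on.
#' @return Data frame: `gene_id`, `module`, `group`, `kwithin`.
#' @export
connectivity_table <- function(expr, design, modules, beta = 12,
                               signed = FALSE) {
  groups <- levels(droplevels(design$exposure))
  out <- lapply(groups, function(g) {
    cols <- design$sample_id[design$exposure == g]
    k <- group_connectivity(expr[, cols, drop = FALSE], modules, beta, signed)
    k$group <- g
    k
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$group <- factor(res$group, levels = groups)
  res[, c("gene_id", "module", "group", "kwithin")]
}

#' Module-level ANOVA for differential connectivity
#'
#' Per module, a one-way ANOVA of gene-level kWithin across exposure
#' groups (each gene contributes one observation per group, following the
#' procedure of the emulated analysis; gene-level values within a module
#' are correlated, so the test is anti-conservative in the strict sense --
#' see the methods vignette). Modules whose kWithin shows no variance at
#' all give F = 0, p = 1; zero within-group variance with a between-group
#' difference gives an infinite F, p = 0, flagged in `degenerate`.
#'
#' @param conn_table Output of [connectivity_table()].
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Data frame per module: `module`, `n_genes`, one `mean_<group>`
#'   column per exposure group, `f`, `p`, `degenerate`, `significant`
#'   (p below `alpha / n_modules`); the threshold is stored in the
#'   `bonferroni` attribute.
#' @export
module_connectivity_anova <- function(conn_table, alpha = 0.05) {
  mods <- sort(unique(conn_table$module))
  groups <- levels(conn_table$group)
  rows <- list()
  for (m in mods) {
    sub <- conn_table[conn_table$module == m, ]
    n_genes <- length(unique(sub$gene_id))
    if (n_genes < 2) {
      warning("module ", m, " has fewer than 2 genes; skipped")
      next
    }
    k <- sub$kwithin
    g <- droplevels(sub$group)
    means <- tapply(k, g, mean)
    grand <- mean(k)
    ssb <- sum(tapply(k, g, length) * (means - grand)^2)
    ssw <- sum((k - means[g])^2)
    df1 <- nlevels(g) - 1
    df2 <- length(k) - nlevels(g)
    degenerate <- FALSE
    if (ssb <= 1e-300 && ssw <= 1e-300) {
      f <- 0; p <- 1
    } else if (ssw <= 1e-300) {
      f <- Inf; p <- 0; degenerate <- TRUE
    } else {
      f <- (ssb / df1) / (ssw / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    row <- data.frame(module = m, n_genes = n_genes, stringsAsFactors = FALSE)
    for (gr in groups) row[[paste0("mean_", gr)]] <- unname(means[gr])
    row$f <- f; row$p <- p; row$degenerate <- degenerate
    rows[[length(rows) + 1]] <- row
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  thr <- bonferroni_threshold(nrow(res), alpha)
  res$significant <- res$p < thr
  attr(res, "bonferroni") <- thr
  attr(res, "alpha") <- alpha
  res
}

#' Bonferroni-corrected per-test threshold
#'
#' `alpha / n_tests`; e.g. 34 module tests at alpha 0.05 give 1.47E-03,
#' 18 behaviour tests give 2.78E-03, 1497 category tests give 3.34E-05.
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate.
#' @return The threshold at full precision; its 3-significant-figure form
#'   is stored in the `signif3` attribute.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a single integer >= 1")
  }
  thr <- alpha / n_tests
  attr(thr, "signif3") <- signif(thr, 3)
  thr
}
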