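#' Filter a category annotation against the analysis universe
#'
#' Intersects every term's gene set with the universe and drops terms left
#' with fewer than `min_term_size` genes.
#'
#' @param annotation Named list term -> gene id vector.
#' @param universe Character vector of analysed gene ids.
#' @param min_term_size Minimum retained term size (10 in the emulated
#'   analysis).
#' @return Named list of filtered gene sets.
#' @export
filter_annotation <- function(annotation, universe, min_term_size = 10) {
  if (!length(universe)) stop("the gene universe is empty")
  out <- lapply(annotation, function(g) intersect(unique(g), universe))
  out[vapply(out, length, 0L) >= min_term_size]
}

#' Fit a probability weighting function for gene-length bias
#'
#' Models the probability that a gene belongs to the test set as a
#' monotone non-decreasing function of gene length: genes are sorted by
#' length into equal-occupancy bins, the per-bin membership proportion is
#' smoothed by isotonic regression, interpolated back to each gene's
#' length, rescaled so the mean weight times the gene count equals the
#' member count, and clamped to `(eps, 1 - eps)`. Constant lengths give a
#' flat PWF equal to the overall membership rate.
#'
#' @param member Logical vector: gene in the test set.
#' @param lengths Numeric gene lengths (same order).
#' @param n_bins Number of length bins (default scales with gene count).
#' @param eps Clamping bound.
#' @return Object of class `pwf`: list with `weights` (named like
#'   `lengths` if named), `bins` (bin table) and `flat`.
#' @export
fit_pwf <- function(member, lengths, n_bins = NULL, eps = 1e-6) {
  member <- as.logical(member)
  if (length(member) != length(lengths)) stop("member and lengths differ in length")
  if (!any(member) || all(member)) {
    stop("need at least one member and one non-member gene")
  }
  n <- length(member)
  if (length(unique(lengths)) == 1) {
    w <- rep(mean(member), n)
    return(structure(list(weights = stats::setNames(w, names(lengths)),
                          bins = NULL, flat = TRUE), class = "pwf"))
  }
  if (is.null(n_bins)) n_bins <- max(5, min(20, floor(n / 200)))
  ord <- order(lengths)
  bin <- ceiling(seq_along(ord) / (n / n_bins))
  bin_prop <- tapply(member[ord], bin, mean)
  bin_len <- tapply(lengths[ord], bin, mean)
  iso <- stats::isoreg(bin_len, bin_prop)
  w <- stats::approx(bin_len, iso$yf, xout = lengths, rule = 2)$y
  w <- w * sum(member) / sum(w)
  w <- pmin(pmax(w, eps), 1 - eps)
  structure(list(weights = stats::setNames(w, names(lengths)),
                 bins = data.frame(length = as.numeric(bin_len),
                                   proportion = as.numeric(bin_prop),
                                   fitted = iso$yf),
                 flat = FALSE), class = "pwf")
}

#' Wallenius noncentral hypergeometric mass function
#'
#' Exact distribution of the number of "white" genes drawn when `n` genes
#' are sampled without replacement from `m1` white and `m2` black genes,
#' each white gene having odds `w` relative to a black gene, computed by
#' the sequential-draw recurrence (dynamic programme over the number of
#' white genes drawn). The central case `w = 1` is the ordinary
#' hypergeometric.
#'
#' @param m1,m2 White/black population sizes.
#' @param n Number of draws (`<= m1 + m2`).
#' @param w Odds of a white gene (> 0).
#' @return Numeric vector of probabilities for counts `0..n`.
#' @export
wallenius_pmf <- function(m1, m2, n, w) {
  if (w <= 0) stop("odds w must be > 0")
  if (n > m1 + m2) stop("cannot draw more genes than the universe holds")
  p <- numeric(n + 1)   # p[k+1] = P(k white after t draws)
  p[1] <- 1
  if (n == 0) return(p)
  for (t in 0:(n - 1)) {
    k <- 0:t
    white_left <- pmax(m1 - k, 0)
    black_left <- pmax(m2 - (t - k), 0)
    denom <- w * white_left + black_left
    pw <- ifelse(denom > 0, w * white_left / denom, 0)
    cur <- p[1:(t + 1)]
    nxt <- numeric(t + 2)
    nxt[1:(t + 1)] <- cur * (1 - pw)
    nxt[2:(t + 2)] <- nxt[2:(t + 2)] + cur * pw
    p[1:(t + 2)] <- nxt
    if (t + 2 <= n) p[(t + 3):(n + 1)] <- 0
  }
  p
}

#' Wallenius over-representation test for one term
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a term and a module under biased sampling without replacement, with the
#' term's odds derived from the PWF: `w = [mean w_in / (1 - mean w_in)] /
#' [mean w_out / (1 - mean w_out)]` over genes inside/outside the term.
#'
#' @param term_genes,module_genes Gene id vectors (subsets of `universe`).
#' @param universe Analysed gene ids.
#' @param pwf A [fit_pwf()] object or a numeric weight vector aligned with
#'   `universe`.
#' @return Upper-tail p-value.
#' @export
wallenius_term_test <- function(term_genes, module_genes, universe, pwf) {
  weights <- pwf_weights(pwf, universe)
  term_genes <- intersect(term_genes, universe)
  module_genes <- intersect(module_genes, universe)
  n <- length(module_genes)
  if (n == 0) return(1)
  m1 <- length(term_genes)
  m2 <- length(universe) - m1
  x <- length(intersect(term_genes, module_genes))
  inside <- universe %in% term_genes
  w_in <- mean(weights[inside]); w_out <- mean(weights[!inside])
  w <- (w_in / (1 - w_in)) / (w_out / (1 - w_out))
  pmf <- wallenius_pmf(m1, m2, n, w)
  min(1, sum(pmf[(x + 1):(n + 1)]))
}

#' Sampling-based null for the over-representation test
#'
#' Monte-Carlo oracle for [wallenius_term_test()]: draws `n_draws` modules
#' of the observed size by weighted sampling without replacement with
#' probabilities proportional to the PWF, and reports
#' `(1 + #draws with overlap >= observed) / (1 + n_draws)`.
#'
#' @inheritParams wallenius_term_test
#' @param n_draws Number of Monte-Carlo draws (< 100 triggers a warning).
#' @param seed Integer seed.
#' @return Monte-Carlo p-value.
#' @export
sampling_null_test <- function(term_genes, module_genes, universe, pwf,
                               n_draws = 10000, seed = 1L) {
  if (n_draws < 100) warning("fewer than 100 draws; the p-value will be coarse")
  weights <- pwf_weights(pwf, universe)
  term_genes <- intersect(term_genes, universe)
  module_genes <- intersect(module_genes, universe)
  n <- length(module_genes)
  if (n == 0) return(1)
  x <- length(intersect(term_genes, module_genes))
  in_term <- universe %in% term_genes
  set.seed(seed)
  hits <- 0L
  idx <- seq_along(universe)
  for (i in seq_len(n_draws)) {
    draw <- sample(idx, n, prob = weights)
    if (sum(in_term[draw]) >= x) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_draws)
}

pwf_weights <- function(pwf, universe) {
  w <- if (inherits(pwf, "pwf")) pwf$weights else pwf
  if (length(w) != length(universe)) {
    stop("PWF weights must align with the universe")
  }
  if (!is.null(names(w))) w <- w[universe]
  as.numeric(w)
}

#' Per-module category enrichment
#'
#' For each tested module: fits a PWF with membership "gene in this
#' module" against the full analysed universe, then tests every retained
#' term for over-representation with the Wallenius approximation. The
#' Bonferroni family is the set of distinct retained terms annotating at
#' least one gene of any tested module.
#'
#' @param module_genes Named list module label -> gene id vector (the
#'   connectivity-significant modules).
#' @param annotation Named list term -> gene ids (unfiltered).
#' @param lengths Named gene lengths covering the universe.
#' @param universe Analysed gene ids (default: names of `lengths`).
#' @param alpha Family-wise error rate.
#' @param min_term_size Passed to [filter_annotation()].
#' @return Data frame: `module`, `term`, `overlap`, `term_size`,
#'   `module_size`, `p`, `significant`; attributes `bonferroni` and
#'   `n_terms` (family size).
#' @export
module_enrichment <- function(module_genes, annotation, lengths,
                              universe = names(lengths), alpha = 0.05,
                              min_term_size = 10) {
  ann <- filter_annotation(annotation, universe, min_term_size)
  if (!length(module_genes) || !length(ann)) {
    res <- data.frame(module = character(0), term = character(0),
                      overlap = integer(0), term_size = integer(0),
                      module_size = integer(0), p = numeric(0),
                      significant = logical(0))
    attr(res, "n_terms") <- 0L
    return(res)
  }
  all_mod_genes <- unique(unlist(module_genes))
  family <- names(ann)[vapply(ann, function(g)
    length(intersect(g, all_mod_genes)) > 0, TRUE)]
  thr <- bonferroni_threshold(max(1L, length(family)), alpha)
  len_u <- lengths[universe]
  rows <- list()
  for (m in names(module_genes)) {
    mg <- intersect(module_genes[[m]], universe)
    member <- universe %in% mg
    pwf <- fit_pwf(member, len_u)
    for (tm in family) {
      p <- wallenius_term_test(ann[[tm]], mg, universe, pwf)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, term = tm,
        overlap = length(intersect(ann[[tm]], mg)),
        term_size = length(ann[[tm]]), module_size = length(mg),
        p = p, significant = p < thr, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "bonferroni") <- thr
  attr(res, "n_terms") <- length(family)
  res
}

#' Export a term-overlap map
#'
#' Writes term pairs sharing genes (within the significant enrichment
#' results) as a node/edge list for external graph viewers: `term1 TAB
#' term2 TAB shared_genes`.
#'
#' @param annotation Filtered annotation list.
#' @param terms Terms to include.
#' @param path Output file.
#' @export
write_term_overlap <- function(annotation, terms, path) {
  terms <- intersect(terms, names(annotation))
  lines <- character(0)
  if (length(terms) >= 2) {
    for (i in seq_len(length(terms) - 1)) {
      for (j in (i + 1):length(terms)) {
        shared <- length(intersect(annotation[[terms[i]]], annotation[[terms[j]]]))
        if (shared > 0) {
          lines <- c(lines, sprintf("%s\t%s\t%d", terms[i], terms[j], shared))
        }
      }
    }
  }
  writeLines(c("term1\tterm2\tshared_genes", lines), path)
  invisible(path)
}
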