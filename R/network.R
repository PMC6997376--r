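#' Gene-gene Pearson correlation
#'
#' Correlation across samples between all gene pairs. Zero-variance genes
#' get correlation 0 to every other gene (and are reported in the
#' `zero_variance` attribute with a warning) so downstream adjacency stays
#' defined.
#'
#' @param expr Expression matrix, genes in rows, >= 3 samples.
#' @return Symmetric correlation matrix, unit diagonal, entries in `[-1,1]`.
#' @export
gene_correlation <- function(expr) {
  if (ncol(expr) < 3) stop("need at least 3 samples to correlate genes")
  sds <- apply(expr, 1, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(t(expr)))
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s); their correlations set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  attr(r, "zero_variance") <- rownames(expr)[flat]
  r
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + r_ij) / 2)^beta`: correlation -1 maps to 0, +1 to 1, and
#' the soft-threshold power emphasizes strong positive co-expression while
#' keeping the network weighted.
#'
#' @param cor_mat Correlation matrix.
#' @param beta Soft-threshold power (>= 1; 12 in the emulated analysis).
#' @return Adjacency matrix in `[0,1]` with unit diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta = 12) {
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{j != i} a_ij` and the sum over shared
#' neighbours `u != i, j`; `TOM_ii = 1`. `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adjacency Valid adjacency matrix (symmetric, `[0,1]`, unit
#'   diagonal).
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) stop("adjacency must lie in [0,1]")
  a0 <- adjacency
  diag(a0) <- 0
  shared <- a0 %*% a0          # u ranges over all genes; diag-0 removes u=i,j
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut by a
#' simplified dynamic rule: descending from the dendrogram root, a merge is
#' split when it lies above `cut_height` times the tree height (static
#' component), or when both children hold at least `min_module_size` genes
#' and the merge sits above its children by more than `gap_frac` of the
#' height range (gap component). Resulting clusters smaller than
#' `min_module_size` become module 0 (unassigned); remaining modules are
#' relabelled 1..M by descending size.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size Smallest retained module (20 in the emulated
#'   analysis).
#' @param cut_height Static cut as a fraction of the maximum merge height.
#' @param gap_frac Minimum merge-height gap (fraction of the height range)
#'   for a dynamic split.
#' @return Named integer vector gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = 0.99,
                           gap_frac = 0.25) {
  n <- nrow(tom)
  ids <- rownames(tom) %||% as.character(seq_len(n))
  if (n < min_module_size) {
    return(stats::setNames(integer(n), ids))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- cut_dendrogram(hc, n, min_module_size, cut_height, gap_frac)
  relabel_by_size(labels, min_module_size, ids)
}

# Simplified dynamic cut over the hclust merge tree (iterative: no deep
# recursion on large trees).
cut_dendrogram <- function(hc, n, min_size, cut_height, gap_frac) {
  m <- hc$merge
  heights <- hc$height
  n_nodes <- nrow(m)
  if (n_nodes == 0) return(rep(1L, n))
  h_max <- max(heights)
  h_range <- h_max - min(heights)
  h_static <- cut_height * h_max
  node_size <- integer(n_nodes)
  node_height <- heights
  child_height <- function(ch) if (ch < 0) 0 else node_height[ch]
  child_size <- function(ch) if (ch < 0) 1L else node_size[ch]
  for (i in seq_len(n_nodes)) {
    node_size[i] <- child_size(m[i, 1]) + child_size(m[i, 2])
  }
  # decide split top-down; collect cluster root nodes
  cluster_roots <- list()
  stack <- list(n_nodes)     # node indices (positive) or leaves (negative)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node < 0) { cluster_roots[[length(cluster_roots) + 1]] <- node; next }
    h <- node_height[node]
    ch1 <- m[node, 1]; ch2 <- m[node, 2]
    gap <- h - max(child_height(ch1), child_height(ch2))
    split_static <- h > h_static
    split_gap <- h_range > 0 && gap > gap_frac * h_range &&
      child_size(ch1) >= min_size && child_size(ch2) >= min_size
    if (split_static || split_gap) {
      stack[[length(stack) + 1]] <- ch1
      stack[[length(stack) + 1]] <- ch2
    } else {
      cluster_roots[[length(cluster_roots) + 1]] <- node
    }
  }
  labels <- integer(n)
  for (ci in seq_along(cluster_roots)) {
    root <- cluster_roots[[ci]]
    stack <- list(root)
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (nd < 0) {
        labels[-nd] <- ci
      } else {
        stack[[length(stack) + 1]] <- m[nd, 1]
        stack[[length(stack) + 1]] <- m[nd, 2]
      }
    }
  }
  labels
}

relabel_by_size <- function(labels, min_size, ids) {
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[tab >= min_size])
  out <- integer(length(labels))
  if (length(keep)) {
    sizes <- tab[as.character(keep)]
    ord <- keep[order(-sizes, keep)]
    for (j in seq_along(ord)) out[labels == ord[j]] <- j
  }
  stats::setNames(out, ids)
}

#' Partition genes into blocks for blockwise module detection
#'
#' A single block when the gene count fits `max_block_size`; otherwise
#' genes are pre-clustered by k-means on their expression profiles into
#' `ceiling(n / max_block_size)` centres, then rebalanced (farthest members
#' of oversized clusters moved to the nearest centre with room) so no block
#' exceeds the limit.
#'
#' @param expr Expression matrix, genes in rows.
#' @param max_block_size Maximum genes per block (5000 in the emulated
#'   analysis).
#' @return List of integer gene-index vectors.
#' @export
blockwise_partition <- function(expr, max_block_size = 5000) {
  n <- nrow(expr)
  if (n <= max_block_size) return(list(seq_len(n)))
  k <- ceiling(n / max_block_size)
  km <- stats::kmeans(expr, centers = k, nstart = 3, iter.max = 50)
  assign <- km$cluster
  centers <- km$centers
  repeat {
    sizes <- tabulate(assign, k)
    over <- which(sizes > max_block_size)
    if (!length(over)) break
    b <- over[1]
    members <- which(assign == b)
    d_own <- rowSums((expr[members, , drop = FALSE] -
                        matrix(centers[b, ], length(members), ncol(expr),
                               byrow = TRUE))^2)
    excess <- sizes[b] - max_block_size
    move <- members[order(-d_own)][seq_len(excess)]
    room <- which(sizes < max_block_size)
    room <- setdiff(room, b)
    for (g in move) {
      d_alt <- vapply(room, function(cc)
        sum((expr[g, ] - centers[cc, ])^2), 0)
      dest <- room[which.min(d_alt)]
      assign[g] <- dest
      sizes[dest] <- sizes[dest] + 1L
      if (sizes[dest] >= max_block_size) room <- setdiff(room, dest)
    }
  }
  lapply(seq_len(k), function(b) which(assign == b))
}

#' Blockwise signed network construction and module detection
#'
#' Runs correlation -> signed adjacency -> TOM -> module detection within
#' each block from [blockwise_partition()] and relabels the union of
#' modules by descending size. Zero-variance genes are dropped to module 0
#' with a warning before correlation.
#'
#' @param expr log2-normalized expression (genes x samples).
#' @param beta Soft-threshold power.
#' @param min_module_size,cut_height,gap_frac Passed to [detect_modules()].
#' @param max_block_size Passed to [blockwise_partition()].
#' @return Named integer vector gene -> module label.
#' @export
build_network_modules <- function(expr, beta = 12, min_module_size = 20,
                                  cut_height = 0.99, gap_frac = 0.25,
                                  max_block_size = 5000) {
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  sds <- apply(expr, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("dropping ", sum(flat), " zero-variance gene(s) to module 0")
  }
  labels <- stats::setNames(integer(nrow(expr)), ids)
  use <- which(!flat)
  if (!length(use)) return(labels)
  sub <- expr[use, , drop = FALSE]
  blocks <- blockwise_partition(sub, max_block_size)
  raw <- integer(nrow(sub))
  offset <- 0L
  for (blk in blocks) {
    e <- sub[blk, , drop = FALSE]
    tom <- topological_overlap(signed_adjacency(gene_correlation(e), beta))
    lab <- detect_modules(tom, min_module_size, cut_height, gap_frac)
    raw[blk] <- ifelse(lab > 0, lab + offset, 0L)
    offset <- offset + max(0L, max(lab))
  }
  labels[use] <- relabel_by_size(raw, min_module_size, NULL)
  labels
}

#' Export a weighted edge list
#'
#' Upper-triangle edges of an adjacency matrix as `gene1 TAB gene2 TAB
#' weight` with fixed 6-decimal formatting, for external graph viewers.
#'
#' @param adjacency Adjacency matrix with gene ids as dimnames.
#' @param path Output file.
#' @param threshold Minimum weight for an edge to be written.
#' @export
write_edge_list <- function(adjacency, path, threshold = 0) {
  ids <- rownames(adjacency)
  ut <- which(upper.tri(adjacency), arr.ind = TRUE)
  w <- adjacency[ut]
  keep <- w >= threshold
  lines <- sprintf("%s\t%s\t%.6f", ids[ut[keep, 1]], ids[ut[keep, 2]], w[keep])
  writeLines(c("gene1\tgene2\tweight", lines), path)
  invisible(path)
}
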