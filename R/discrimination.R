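# ---- agreement indices -----------------------------------------------------

# internal: generalized "choose 2" that accepts non-integer (reweighted) counts
pairs2 <- function(x) x * (x - 1) / 2

# internal: contingency table of two partitions
partition_table <- function(a, b) {
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two partitions of the
#' same items; 1 for identical partitions, expectation 0 under random
#' labeling.
#'
#' @param a,b partition label vectors of equal length (any atomic type), or
#'   pass a precomputed contingency `table` instead.
#' @param table optional contingency table overriding `a`/`b`.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b, table = NULL) {
  ct <- if (is.null(table)) partition_table(a, b) else table
  n <- sum(ct)
  sij <- sum(pairs2(ct))
  si <- sum(pairs2(rowSums(ct)))
  sj <- sum(pairs2(colSums(ct)))
  expected <- si * sj / pairs2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1) # both partitions trivial
  (sij - expected) / (maxi - expected)
}

# internal: entropy of a (possibly weighted) marginal, natural log
entropy_nat <- function(w) {
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

# internal: exact expected mutual information under the permutation
# (hypergeometric) model, natural log; integer marginals required
expected_mi <- function(ai, bj, n) {
  emi <- 0
  lfac <- lfactorial
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      lp <- lfac(ai[i]) + lfac(bj[j]) + lfac(n - ai[i]) + lfac(n - bj[j]) -
        lfac(n) - lfac(nij) - lfac(ai[i] - nij) - lfac(bj[j] - nij) -
        lfac(n - ai[i] - bj[j] + nij)
      emi <- emi + sum(exp(lp) * nij / n * log(n * nij / (ai[i] * bj[j])))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two partitions, corrected by its exact
#' expectation under the permutation model and normalized by the arithmetic
#' mean of the two entropies (the common default of clustering-metric
#' libraries); 1 for identical partitions, expectation 0 at random.
#'
#' @inheritParams adjusted_rand_index
#' @return the AMI.
#' @export
adjusted_mutual_info <- function(a, b, table = NULL) {
  ct <- if (is.null(table)) partition_table(a, b) else table
  n <- sum(ct)
  ai <- rowSums(ct); bj <- colSums(ct)
  nz <- which(ct > 0, arr.ind = TRUE)
  v <- ct[nz]
  mi <- sum(v / n * log(n * v / (ai[nz[, 1]] * bj[nz[, 2]])))
  h <- (entropy_nat(ai) + entropy_nat(bj)) / 2
  emi <- expected_mi(ai, bj, n)
  if (abs(h - emi) < 1e-15) return(ifelse(abs(mi - emi) < 1e-15, 1, 0))
  (mi - emi) / (h - emi)
}

# internal: reweight contingency rows (true classes) to equal mass,
# preserving the grand total
balance_table <- function(ct) {
  rs <- rowSums(ct)
  keep <- rs > 0
  ct <- ct[keep, , drop = FALSE]
  rs <- rs[keep]
  n <- sum(rs)
  sweep(ct, 1, (n / nrow(ct)) / rs, `*`)
}

#' Balanced adjusted Rand index
#'
#' [adjusted_rand_index()] computed after reweighting each true class (the
#' rows of the contingency table) to equal mass, so rare cell types count as
#' much as abundant ones. Equals the plain ARI when classes are exactly
#' equal-sized. Pair counts use the continuous extension x(x-1)/2.
#'
#' @param labels true class labels (the balanced margin).
#' @param clusters cluster assignments.
#' @return the balanced ARI.
#' @export
balanced_adjusted_rand_index <- function(labels, clusters) {
  adjusted_rand_index(table = balance_table(partition_table(labels, clusters)))
}

#' Balanced adjusted mutual information
#'
#' [adjusted_mutual_info()] on the class-rebalanced contingency table. The
#' expected-MI correction needs integer marginals, so the balanced table is
#' rounded to its total-preserving integer approximation.
#'
#' @inheritParams balanced_adjusted_rand_index
#' @return the balanced AMI.
#' @export
balanced_adjusted_mutual_info <- function(labels, clusters) {
  bt <- balance_table(partition_table(labels, clusters))
  adjusted_mutual_info(table = round(bt))
}

# ---- embedding scores ------------------------------------------------------

#' Average silhouette width of labels on an embedding, on the [0, 1] scale
#'
#' Mean silhouette of the label groups under Euclidean distance, mapped from
#' \[-1, 1\] to \[0, 1\] via `(s + 1) / 2`.
#'
#' @param labels per-cell labels (>= 2 distinct).
#' @param embedding numeric matrix, one row per cell.
#' @return the rescaled average silhouette width.
#' @export
average_silhouette_width <- function(labels, embedding) {
  stopifnot_msg(length(labels) == nrow(embedding),
                "one embedding row per label required")
  stopifnot_msg(length(unique(labels)) >= 2, "need >= 2 distinct labels")
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(embedding))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Cumulative variance ratio of the first principal components
#'
#' The summed variance fractions of the first `n_components` PCs of the
#' embedding (default 10); 1 when the embedding's intrinsic dimension does
#' not exceed `n_components`.
#'
#' @param embedding numeric matrix, one row per cell.
#' @param n_components number of leading components (default 10).
#' @return the cumulative variance ratio in (0, 1].
#' @export
cumulative_variance_ratio <- function(embedding, n_components = 10) {
  pc <- prcomp(embedding, center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  sum(vr[seq_len(min(n_components, length(vr)))])
}

#' All partition scores for one kit
#'
#' ARI and AMI between the clustering and the labels, their class-balanced
#' variants, the rescaled average silhouette width of the labels on the
#' embedding, and the cumulative variance ratio of the embedding's first 10
#' PCs.
#'
#' @param clusters cluster assignments.
#' @param labels reference labels of equal length.
#' @param embedding cells x dims numeric matrix.
#' @return named numeric vector `c(ari, ami, bari, bami, asw, cvr)`.
#' @export
partition_scores <- function(clusters, labels, embedding) {
  stopifnot_msg(length(clusters) == length(labels),
                "clusters and labels must have equal length")
  c(ari = adjusted_rand_index(labels, clusters),
    ami = adjusted_mutual_info(labels, clusters),
    bari = balanced_adjusted_rand_index(labels, clusters),
    bami = balanced_adjusted_mutual_info(labels, clusters),
    asw = average_silhouette_width(labels, embedding),
    cvr = cumulative_variance_ratio(embedding))
}

# ---- clustering ------------------------------------------------------------

# internal: shared-nearest-neighbor graph from an embedding (exact kNN)
snn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d <- as.matrix(dist(embedding))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  # adjacency of the kNN relation, symmetrized; weight = shared neighbors
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)
  mutual <- ((adj + Matrix::t(adj)) > 0) * 1
  w <- shared * mutual
  Matrix::diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  g
}

#' Leiden clustering of an embedding at one resolution
#'
#' Builds a shared-nearest-neighbor graph from the embedding and runs the
#' Leiden algorithm with the modularity objective.
#'
#' @param embedding cells x dims numeric matrix, or a precomputed igraph.
#' @param resolution modularity resolution parameter.
#' @param k neighbors for the SNN graph (ignored for a graph input).
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return integer vector of cluster memberships.
#' @export
leiden_clusters <- function(embedding, resolution, k = 15, seed = 1) {
  g <- if (inherits(embedding, "igraph")) embedding else snn_graph(embedding, k)
  with_seed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    igraph::membership(cl)
  })
}

#' Scan Leiden resolutions for the label-matched optimum
#'
#' Clusters the embedding at every resolution on the grid (default 0.02 to
#' 1.00 in steps of 0.02) and selects the lowest resolution whose cluster
#' count is closest to the number of distinct labels.
#'
#' @param embedding cells x dims numeric matrix or an igraph.
#' @param labels per-cell reference labels.
#' @param resolution_grid increasing vector of resolutions.
#' @param k SNN neighbors.
#' @param seed integer seed.
#' @return list with `resolution`, `clusters`, `n_clusters`, `scan` (a
#'   data.frame of the whole grid).
#' @export
optimal_resolution_scan <- function(embedding, labels,
                                    resolution_grid = seq(0.02, 1.00, by = 0.02),
                                    k = 15, seed = 1) {
  stopifnot_msg(length(resolution_grid) >= 1, "empty resolution grid")
  stopifnot_msg(length(labels) >= 2, "labels required")
  g <- if (inherits(embedding, "igraph")) embedding else snn_graph(embedding, k)
  n_labels <- length(unique(labels))
  runs <- lapply(seq_along(resolution_grid), function(i)
    leiden_clusters(g, resolution_grid[i], seed = seed + i))
  n_cl <- vapply(runs, function(cl) length(unique(cl)), integer(1))
  diff_ <- abs(n_cl - n_labels)
  best <- which(diff_ == min(diff_))[1] # lowest resolution among ties
  list(resolution = resolution_grid[best],
       clusters = as.integer(runs[[best]]),
       n_clusters = n_cl[best],
       scan = data.frame(resolution = resolution_grid, n_clusters = n_cl,
                         diff = diff_))
}

# ---- differential expression ----------------------------------------------

# internal: vectorized two-sided Wilcoxon rank-sum tests of group vs rest,
# normal approximation with tie correction (the convention of single-cell
# rank-test implementations)
wilcox_vs_rest <- function(m, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  z <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    r <- rank(x)
    R1 <- sum(r[in_group])
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(0)
    (R1 - mu) / sqrt(sigma2)
  }, numeric(1))
  2 * pnorm(-abs(z))
}

# internal: log2 fold change on expm1 of mean log1p CPM, with pseudocount
log2_fold_change <- function(norm, in_group, pseudo = 1e-9) {
  mean_in <- Matrix::colMeans(log1p(norm[in_group, , drop = FALSE]))
  mean_out <- Matrix::colMeans(log1p(norm[!in_group, , drop = FALSE]))
  log2((expm1(mean_in) + pseudo) / (expm1(mean_out) + pseudo))
}

#' One-vs-rest differential expression per cell type
#'
#' Subsamples the cells (without replacement) to `n_subsample`, drops cell
#' types with fewer than `min_cells` cells, and for each remaining type runs
#' a two-sided Wilcoxon rank-sum test of every gene against all other cells.
#' A gene is a significant DEG for a type iff its log2 fold change exceeds
#' `lfc_min` and its Benjamini-Hochberg-adjusted p value is below `alpha`
#' (adjustment within each type's gene family).
#'
#' @param dataset a [kit_dataset()].
#' @param labels per-cell cell-type labels (defaults to the dataset's).
#' @param n_subsample cells to keep (study default 3457); `NULL` keeps all.
#' @param min_cells minimal type size to be tested (default 10).
#' @param lfc_min log2 fold-change cutoff (default 2, exclusive).
#' @param alpha BH-adjusted p cutoff (default 0.05, exclusive).
#' @param seed integer seed for the subsample.
#' @return object of class `deg_result`: list with `counts` (named per-type
#'   DEG counts), `genes` (per-type character vectors), `table` (data.frame
#'   `cell_type`, `gene`, `lfc`, `p_adj` of significant DEGs).
#' @export
deg_one_vs_rest <- function(dataset, labels = dataset$cell_labels,
                            n_subsample = 3457, min_cells = 10,
                            lfc_min = 2, alpha = 0.05, seed = 1) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  stopifnot_msg(!is.null(labels) && length(labels) == nrow(dataset$counts),
                "per-cell labels required")
  m <- dataset$counts
  if (!is.null(n_subsample) && nrow(m) > n_subsample) {
    idx <- with_seed(seed, sort(sample.int(nrow(m), n_subsample)))
    m <- m[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  tab <- table(labels)
  types <- names(tab)[tab >= min_cells]
  stopifnot_msg(length(types) >= 2, "fewer than 2 cell types after the size filter")
  norm <- suppressWarnings(cpm_normalize(m))
  dense <- as.matrix(norm) # rank tests need dense columns
  res <- list(); rows <- list()
  for (ct in types) {
    in_group <- labels == ct
    p <- wilcox_vs_rest(dense, in_group)
    p_adj <- p.adjust(p, method = "BH")
    lfc <- log2_fold_change(norm, in_group)
    sig <- which(lfc > lfc_min & p_adj < alpha)
    res[[ct]] <- colnames(m)[sig]
    if (length(sig))
      rows[[ct]] <- data.frame(cell_type = ct, gene = colnames(m)[sig],
                               lfc = lfc[sig], p_adj = p_adj[sig],
                               row.names = NULL)
  }
  structure(list(counts = vapply(res, length, integer(1)),
                 genes = res,
                 table = if (length(rows)) do.call(rbind, rows) else
                   data.frame(cell_type = character(), gene = character(),
                              lfc = numeric(), p_adj = numeric())),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("<deg_result> DEG counts per cell type:\n")
  print(x$counts)
  invisible(x)
}

#' Z-score DEG counts across kits
#'
#' Per cell type (column), standardizes the DEG counts across kits:
#' `z = (count - mean) / sd`; a type with zero across-kit SD gets z = 0.
#'
#' @param deg_counts kits x cell-types numeric matrix (>= 2 kits).
#' @return matrix of z-scores with the same dimnames.
#' @export
deg_zscores <- function(deg_counts) {
  stopifnot_msg(is.matrix(deg_counts) && nrow(deg_counts) >= 2,
                "`deg_counts` must be a matrix with >= 2 kits")
  z <- apply(deg_counts, 2, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  dimnames(z) <- dimnames(deg_counts)
  z
}
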