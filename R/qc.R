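#' Count-matrix preprocessing chain
#'
#' Applies, in this fixed order: (1) remove cells with fewer than
#' `min_genes` detected genes; (2) remove cells with doublet score at or
#' above `doublet_threshold` (inclusive); (3) randomly subsample to
#' `n_subsample` cells without replacement if more remain, otherwise keep
#' all cells with a warning; (4) remove genes detected in fewer than
#' `min_cells_per_gene` cells. The order matters and is part of the
#' contract.
#'
#' @param dataset a [kit_dataset()].
#' @param min_genes minimal detected genes for a cell to survive (default 5).
#' @param doublet_threshold doublet-score removal threshold, inclusive
#'   (default 0.25); `NULL` skips the step (also skipped with a warning when
#'   the dataset carries no scores).
#' @param n_subsample target cell count (default 7750); `NULL` skips.
#' @param min_cells_per_gene minimal cells a gene must appear in (default 3).
#' @param seed integer seed for the subsampling step.
#' @return a filtered [kit_dataset()]; attribute `"subsample_exempt"` is
#'   TRUE when the dataset had fewer cells than `n_subsample`.
#' @export
preprocess <- function(dataset, min_genes = 5, doublet_threshold = 0.25,
                       n_subsample = 7750, min_cells_per_gene = 3, seed = 1) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  m <- dataset$counts
  keep <- Matrix::rowSums(m > 0) >= min_genes

  if (!is.null(doublet_threshold)) {
    if (is.null(dataset$doublet_scores)) {
      warning("no doublet scores on dataset; skipping doublet filter")
    } else {
      keep <- keep & dataset$doublet_scores < doublet_threshold
    }
  }
  idx <- which(keep)

  exempt <- FALSE
  if (!is.null(n_subsample)) {
    if (length(idx) > n_subsample) {
      idx <- sort(with_seed(seed, sample(idx, n_subsample)))
    } else if (length(idx) < n_subsample) {
      exempt <- TRUE
      warning("fewer cells (", length(idx), ") than n_subsample (",
              n_subsample, "); keeping all")
    }
  }

  m <- m[idx, , drop = FALSE]
  gene_keep <- Matrix::colSums(m > 0) >= min_cells_per_gene
  m <- m[, gene_keep, drop = FALSE]
  if (nrow(m) == 0) warning("preprocessing removed all cells")

  out <- kit_dataset(m, dataset$barcodes[idx],
                     dataset$genes[gene_keep, , drop = FALSE],
                     dataset$kit_id, dataset$replicate_id,
                     cell_labels = dataset$cell_labels[idx],
                     doublet_scores = dataset$doublet_scores[idx])
  attr(out, "subsample_exempt") <- exempt
  out
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell: detected genes, total UMIs, and the percentage of
#' UMIs in mitochondrial and ribosomal-protein genes. Genes are classified
#' by symbol prefix: `MT-` for mitochondrial, `RPS`/`RPL` for ribosomal
#' protein (case-sensitive, configurable).
#'
#' @param dataset a [kit_dataset()].
#' @param mt_prefixes,rp_prefixes character vectors of gene-symbol prefixes.
#' @return data.frame (`qc_table`) with columns `barcode`, `n_genes`,
#'   `n_umis`, `pct_mt`, `pct_rp`.
#' @export
percell_qc <- function(dataset, mt_prefixes = "MT-",
                       rp_prefixes = c("RPS", "RPL")) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  sym <- dataset$genes$symbol
  stopifnot_msg(!is.null(sym), "gene symbols required")
  has_prefix <- function(prefixes)
    Reduce(`|`, lapply(prefixes, function(p) startsWith(sym, p)))
  mt <- has_prefix(mt_prefixes)
  rp <- has_prefix(rp_prefixes)
  m <- dataset$counts
  total <- Matrix::rowSums(m)
  if (any(total == 0))
    warning(sum(total == 0), " cells with zero total UMIs; their percentages set to 0")
  pct <- function(sel) {
    s <- if (any(sel)) Matrix::rowSums(m[, sel, drop = FALSE]) else rep(0, nrow(m))
    ifelse(total > 0, 100 * s / total, 0)
  }
  structure(data.frame(barcode = dataset$barcodes,
                       n_genes = Matrix::rowSums(m > 0),
                       n_umis = total,
                       pct_mt = pct(mt),
                       pct_rp = pct(rp),
                       row.names = NULL),
            class = c("qc_table", "data.frame"))
}

# internal: Dunn's pairwise rank test with tie correction (large-sample z)
dunn_posthoc <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  g <- names(rbar)
  pairs <- utils::combn(g, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             statistic = res["z", ], p_raw = res["p", ],
             row.names = NULL)
}

#' Cross-kit distribution tests for a per-cell metric
#'
#' Kruskal-Wallis omnibus test across kits followed by Dunn's pairwise
#' post-hoc tests (large-sample normal approximation with tie correction),
#' with Bonferroni adjustment over all pairs (adjusted p clipped at 1).
#'
#' @param metric_vectors named list of per-cell metric vectors, one per kit
#'   (>= 2 groups, each with >= 2 observations).
#' @return list with `omnibus_p`, `omnibus_statistic`, and `pairwise` (a
#'   data.frame with `group_a`, `group_b`, `statistic`, `p_raw`, `p_adj`).
#' @export
compare_kits <- function(metric_vectors) {
  stopifnot_msg(is.list(metric_vectors) && length(metric_vectors) >= 2 &&
                  !is.null(names(metric_vectors)),
                "`metric_vectors` must be a named list with >= 2 groups")
  sizes <- lengths(metric_vectors)
  stopifnot_msg(all(sizes >= 2), "every group needs >= 2 observations")
  values <- unlist(metric_vectors, use.names = FALSE)
  groups <- factor(rep(names(metric_vectors), sizes),
                   levels = names(metric_vectors))
  kw <- kruskal.test(values, groups)
  pw <- dunn_posthoc(values, groups)
  pw$p_adj <- pmin(1, pw$p_raw * nrow(pw))
  list(omnibus_p = kw$p.value,
       omnibus_statistic = unname(kw$statistic),
       pairwise = pw)
}
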