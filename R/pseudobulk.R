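#' Pseudobulk expression profile of a sample
#'
#' Per-cell CPM, then `log(1 + x)`, then the mean over cells per gene.
#'
#' @param dataset a [kit_dataset()] (or any cells x genes count matrix).
#' @return object of class `pseudobulk_profile`: list with `sample_id` and
#'   the named per-gene `values`.
#' @export
pseudobulk_expression <- function(dataset) {
  if (inherits(dataset, "kit_dataset")) {
    m <- dataset$counts
    id <- paste(dataset$kit_id, dataset$replicate_id, sep = "/")
  } else {
    m <- as_sparse(dataset)
    id <- "sample"
  }
  stopifnot_msg(nrow(m) >= 1, "need >= 1 cell")
  norm <- suppressWarnings(cpm_normalize(m))
  vals <- Matrix::colMeans(log1p(norm))
  names(vals) <- colnames(m)
  structure(list(sample_id = id, values = vals), class = "pseudobulk_profile")
}

#' @export
print.pseudobulk_profile <- function(x, ...) {
  cat("<pseudobulk_profile> ", x$sample_id, ": ", length(x$values),
      " genes, mean ", signif(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Cross-sample PCA of pseudobulk profiles
#'
#' Restricts to the intersection of expressed genes (nonzero pseudobulk in
#' every sample), centers each gene across samples (no scaling), and runs
#' PCA. Returns sample embeddings, per-gene loadings and the variance
#' fraction of each component.
#'
#' @param profiles list of >= 3 [pseudobulk_expression()] profiles.
#' @return list with `embeddings` (samples x PCs), `loadings` (genes x PCs),
#'   `variance_ratio`, `genes`, `center`.
#' @export
crosskit_pca <- function(profiles) {
  stopifnot_msg(length(profiles) >= 3, "need >= 3 samples")
  gene_sets <- lapply(profiles, function(p) names(p$values)[p$values > 0])
  common <- Reduce(intersect, gene_sets)
  stopifnot_msg(length(common) >= 2, "fewer than 2 commonly expressed genes")
  X <- t(vapply(profiles, function(p) p$values[common],
                numeric(length(common))))
  rownames(X) <- vapply(profiles, function(p) p$sample_id, character(1))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  list(embeddings = pc$x,
       loadings = pc$rotation,
       variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
       genes = common,
       center = pc$center)
}

#' Pearson correlation of loadings or embeddings with a covariate
#'
#' Thin wrapper around Pearson correlation used to relate PC loadings to
#' gene covariates (length, GC) or PC embeddings to sample covariates
#' (total UMIs, mitochondrial expression).
#'
#' @param values numeric vector (e.g. a loading or embedding column).
#' @param covariate numeric vector of equal length (>= 3 points).
#' @return the Pearson correlation coefficient.
#' @export
covariate_correlation <- function(values, covariate) {
  stopifnot_msg(length(values) == length(covariate), "lengths must match")
  ok <- is.finite(values) & is.finite(covariate)
  stopifnot_msg(sum(ok) >= 3, "need >= 3 finite pairs")
  cor(values[ok], covariate[ok], method = "pearson")
}

# internal: per-gene binomial deviance under a constant-proportion null
# with cell-total size factors; 0*log(0) treated as 0
binomial_deviance <- function(m) {
  m <- as_sparse(m)
  n <- Matrix::rowSums(m)      # cell totals
  y_sum <- Matrix::colSums(m)  # gene totals
  N <- sum(n)
  pi_hat <- y_sum / N
  xlogx <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  trip <- Matrix::summary(m)
  agg_by_gene <- function(v) {
    out <- rep(0, ncol(m))
    a <- tapply(v, trip$j, sum)
    out[as.integer(names(a))] <- a
    out
  }
  # saturated-vs-null log-likelihood terms, split over the sparsity pattern:
  # nonzero entries contribute both binomial terms explicitly; zero entries
  # contribute (n_i - 0) log(n_i / (n_i (1 - pi_j))) = -n_i log(1 - pi_j)
  t1 <- agg_by_gene(xlogx(trip$x, n[trip$i] * pi_hat[trip$j]))
  t2_nz <- agg_by_gene(xlogx(n[trip$i] - trip$x,
                             n[trip$i] * (1 - pi_hat[trip$j])))
  n_nz <- agg_by_gene(n[trip$i]) # sum of cell totals over nonzero cells
  log1mp <- ifelse(pi_hat < 1, log(1 - pi_hat), 0)
  t2_zero <- -(N - n_nz) * log1mp
  dev <- 2 * (t1 + t2_nz + t2_zero)
  dev[pi_hat == 0] <- 0
  names(dev) <- colnames(m)
  pmax(dev, 0)
}

#' Select highly deviant genes (HDGs)
#'
#' Ranks genes by binomial deviance under a constant-proportion null with
#' cell-total size factors: a gene whose counts are exactly proportional to
#' cell totals has deviance 0, while genes with structured (e.g.
#' cell-type-specific) expression score high. For multiple samples the
#' deviance is computed per sample and genes are ranked by median rank
#' across samples.
#'
#' @param dataset a [kit_dataset()] or a list of them (multi-sample mode).
#' @param k number of top genes to return; must not exceed the gene count.
#' @return character vector of `k` gene symbols, most deviant first;
#'   attribute `"deviance"` carries the per-gene statistic (single-sample
#'   mode) or the median cross-sample rank (multi-sample mode).
#' @export
select_deviant_genes <- function(dataset, k) {
  single <- inherits(dataset, "kit_dataset")
  if (single) {
    dev <- binomial_deviance(dataset$counts)
    stopifnot_msg(is_count(k) && k <= length(dev), "`k` exceeds the gene count")
    ord <- order(-dev)
    out <- names(dev)[ord][seq_len(k)]
    attr(out, "deviance") <- dev[ord][seq_len(k)]
    return(out)
  }
  stopifnot_msg(is.list(dataset) && length(dataset) >= 1,
                "`dataset` must be a kit_dataset or a list of them")
  devs <- lapply(dataset, function(d) binomial_deviance(d$counts))
  common <- Reduce(intersect, lapply(devs, names))
  stopifnot_msg(is_count(k) && k <= length(common), "`k` exceeds the common gene count")
  # rank 1 = most deviant within each sample; aggregate by median rank
  ranks <- vapply(devs, function(d) rank(-d[common], ties.method = "average"),
                  numeric(length(common)))
  med <- apply(ranks, 1, median)
  ord <- order(med)
  out <- common[ord][seq_len(k)]
  attr(out, "deviance") <- med[ord][seq_len(k)]
  out
}
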