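#' Counts-per-million normalization
#'
#' Scales each cell (row) so its counts sum to one million. Cells with zero
#' total counts are dropped with a warning.
#'
#' @param counts cells x genes matrix (dense or sparse).
#' @return matrix of the same class with row sums of 1e6.
#' @export
cpm_normalize <- function(counts) {
  m <- as_sparse(counts)
  total <- Matrix::rowSums(m)
  if (any(total == 0)) {
    warning(sum(total == 0), " all-zero cells dropped before CPM normalization")
    m <- m[total > 0, , drop = FALSE]
    total <- total[total > 0]
  }
  stopifnot_msg(nrow(m) >= 1, "no non-empty cells left")
  Matrix::Diagonal(x = 1e6 / total) %*% m
}

#' Per-gene dropout rates and pseudobulk CPM
#'
#' The dropout rate of a gene is the fraction of cells in which its CPM
#' value is zero; the pseudobulk value is its mean CPM across cells.
#'
#' @param norm_matrix CPM-normalized cells x genes matrix (see
#'   [cpm_normalize()]).
#' @return data.frame with columns `gene`, `dropout`, `pseudobulk_cpm`.
#' @export
dropout_rates <- function(norm_matrix) {
  m <- as_sparse(norm_matrix)
  stopifnot_msg(nrow(m) >= 1, "need >= 1 cell")
  data.frame(gene = if (!is.null(colnames(m))) colnames(m) else
               sprintf("g%d", seq_len(ncol(m))),
             dropout = 1 - Matrix::colSums(m > 0) / nrow(m),
             pseudobulk_cpm = Matrix::colMeans(m),
             row.names = NULL)
}

#' Fit the exponential dropout decay and GD50
#'
#' Models per-gene dropout as `dropout = exp(-b * x)` where `x` is the
#' pseudobulk CPM; the scale is fixed at 1 so dropout is complete at zero
#' expression. `b` is constrained to \[0, 0.05\] per CPM and its starting
#' value is drawn uniformly on that interval (seeded). The half-maximal
#' dropout expression is `GD50 = -ln(0.5)/b = ln(2)/b` (reported `NA` with a
#' warning when `b = 0`).
#'
#' @param dropout per-gene dropout rates.
#' @param pseudobulk per-gene pseudobulk CPM values (same length).
#' @param seed integer seed for the random initialization.
#' @param b_bounds lower/upper bounds on the decay rate.
#' @return object of class `dropout_fit` with `a` (= 1), `b`, `gd50`,
#'   `residual_norm`; supports [coef()], [predict()] (argument `newx`),
#'   [print()].
#' @export
fit_dropout_decay <- function(dropout, pseudobulk, seed = 1,
                              b_bounds = c(0, 0.05)) {
  stopifnot_msg(length(dropout) == length(pseudobulk),
                "`dropout` and `pseudobulk` must have equal length")
  ok <- is.finite(dropout) & is.finite(pseudobulk)
  stopifnot_msg(sum(ok) >= 5, "need >= 5 genes with finite values")
  stopifnot_msg(length(unique(dropout[ok])) > 1,
                "all dropout values identical; decay fit is undefined")
  y <- dropout[ok]; x <- pseudobulk[ok]
  b0 <- with_seed(seed, runif(1, b_bounds[1], b_bounds[2]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(b = b0),
                       fn = function(p) y - exp(-p[["b"]] * x),
                       lower = b_bounds[1], upper = b_bounds[2],
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  b <- if (!is.null(fit)) fit$par[["b"]] else {
    # 1-D bounded SSE minimization fallback
    optimize(function(b) sum((y - exp(-b * x))^2),
             interval = b_bounds)$minimum
  }
  if (b >= b_bounds[2] - 1e-12)
    warning("decay rate b at its upper bound (", b_bounds[2], ")")
  gd50 <- if (b > 0) log(2) / b else {
    warning("b = 0: dropout does not decay; GD50 undefined")
    NA_real_
  }
  structure(list(a = 1, b = b, gd50 = gd50,
                 residual_norm = sqrt(sum((y - exp(-b * x))^2))),
            class = "dropout_fit")
}

#' @export
print.dropout_fit <- function(x, ...) {
  cat("<dropout_fit> dropout = exp(-b x), b = ", signif(x$b, 6),
      " per CPM, GD50 = ", signif(x$gd50, 6), " CPM\n", sep = "")
  invisible(x)
}

#' @export
coef.dropout_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.dropout_fit <- function(object, newx, ...) exp(-object$b * newx)

#' Entropy-based gene specificity scores
#'
#' For gene `i` over `t` cells, with `p_ij` the CPM proportion of the gene
#' in cell `j` and `p_i` its mean over cells, the specificity is
#' `S_i = (1/t) * sum_j (p_ij / p_i) * log2(p_ij / p_i)`. Zero-expression
#' cells contribute 0 (the `z log z -> 0` limit). `S_i` is 0 for a gene
#' expressed uniformly across cells and `log2(t)` for a gene expressed in a
#' single cell. Genes with `p_i = 0` are excluded and reported `NA`.
#'
#' @param norm_matrix CPM-normalized cells x genes matrix.
#' @return named numeric vector of per-gene specificity scores.
#' @export
gene_specificity <- function(norm_matrix) {
  m <- as_sparse(norm_matrix)
  t_cells <- nrow(m)
  stopifnot_msg(t_cells >= 1, "need >= 1 cell")
  # p_ij: per-cell proportion of each gene (rows sum to 1)
  rs <- Matrix::rowSums(m)
  stopifnot_msg(all(rs > 0), "all-zero cells present; CPM-normalize first")
  p <- Matrix::Diagonal(x = 1 / rs) %*% m
  p_i <- Matrix::colMeans(p)
  # work on nonzero entries only: ratio log2 ratio, zeros contribute 0
  trip <- Matrix::summary(as_sparse(p))
  ratio <- trip$x / p_i[trip$j]
  contrib <- ratio * log2(ratio)
  s <- rep(NA_real_, ncol(m))
  pos <- which(p_i > 0)
  agg <- rep(0, ncol(m))
  tt <- tapply(contrib, trip$j, sum)
  agg[as.integer(names(tt))] <- tt
  s[pos] <- agg[pos] / t_cells
  names(s) <- colnames(m)
  s
}

#' Peak of a specificity-score distribution
#'
#' Location of the global maximum of a Gaussian kernel density estimate
#' (Scott-rule bandwidth) evaluated on a `grid_n`-point grid spanning the
#' observed range.
#'
#' @param s_values numeric vector of >= 10 specificity scores.
#' @param grid_n grid resolution (default 512).
#' @return the peak location.
#' @export
specificity_peak <- function(s_values, grid_n = 512) {
  s_values <- s_values[is.finite(s_values)]
  stopifnot_msg(length(s_values) >= 10, "need >= 10 finite values")
  if (diff(range(s_values)) == 0) return(s_values[1])
  d <- density(s_values, bw = bw_scott(s_values), n = grid_n,
               from = min(s_values), to = max(s_values))
  d$x[which.max(d$y)]
}

#' Paired bootstrap of dropout decay (GD50) and specificity peak
#'
#' For each of `n_boot` iterations: resample `n_sample` cells with
#' replacement, restrict to `common_genes`, CPM-normalize, fit the dropout
#' decay (seeded random initialization per iteration) and compute the
#' specificity-density peak from the same subsample, so the two statistics
#' are paired per iteration. Returns the draws with bootstrap means and
#' percentile 95% confidence intervals.
#'
#' @param dataset a [kit_dataset()].
#' @param n_boot number of bootstrap iterations (>= 2; study default 500).
#' @param n_sample cells per bootstrap resample (study default 7750).
#' @param common_genes optional character vector restricting to the gene
#'   intersection across kits; `NULL` uses all genes.
#' @param seed integer seed.
#' @return object of class `stability_boot`: list with `draws` (data.frame
#'   `iteration`, `b`, `gd50`, `peak`), `mean`, `ci` (2.5/97.5 percentiles),
#'   `n_boot`, `n_sample`.
#' @export
bootstrap_stability <- function(dataset, n_boot = 500, n_sample = 7750,
                                common_genes = NULL, seed = 1) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  stopifnot_msg(is_count(n_boot) && n_boot >= 2, "`n_boot` must be >= 2")
  m <- dataset$counts
  if (!is.null(common_genes)) {
    sel <- colnames(m) %in% common_genes
    stopifnot_msg(any(sel), "no common genes present in the dataset")
    m <- m[, sel, drop = FALSE]
  }
  n_cells <- nrow(m)
  draws <- with_seed(seed, {
    out <- vector("list", n_boot)
    for (it in seq_len(n_boot)) {
      idx <- sample.int(n_cells, n_sample, replace = TRUE)
      sub <- m[idx, , drop = FALSE]
      norm <- suppressWarnings(cpm_normalize(sub))
      dr <- dropout_rates(norm)
      fit <- suppressWarnings(
        fit_dropout_decay(dr$dropout, dr$pseudobulk_cpm,
                          seed = sample.int(.Machine$integer.max, 1)))
      s <- gene_specificity(norm)
      out[[it]] <- data.frame(iteration = it, b = fit$b, gd50 = fit$gd50,
                              peak = specificity_peak(s))
    }
    do.call(rbind, out)
  })
  qs <- function(v) quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(
    draws = draws,
    mean = c(b = mean(draws$b), gd50 = mean(draws$gd50, na.rm = TRUE),
             peak = mean(draws$peak)),
    ci = rbind(b = qs(draws$b), gd50 = qs(draws$gd50), peak = qs(draws$peak)),
    n_boot = n_boot, n_sample = n_sample, kit_id = dataset$kit_id
  ), class = "stability_boot")
}

#' @export
print.stability_boot <- function(x, ...) {
  cat("<stability_boot> ", x$kit_id, ": ", x$n_boot, " iterations of ",
      x$n_sample, " cells\n", sep = "")
  cat("  mean GD50 = ", signif(x$mean[["gd50"]], 5), " CPM (95% CI ",
      signif(x$ci["gd50", 1], 5), "-", signif(x$ci["gd50", 2], 5), ")\n", sep = "")
  cat("  mean specificity peak = ", signif(x$mean[["peak"]], 5), " (95% CI ",
      signif(x$ci["peak", 1], 5), "-", signif(x$ci["peak", 2], 5), ")\n", sep = "")
  invisible(x)
}
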