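#' Depth-downsample a dataset by per-molecule read thinning
#'
#' Emulates resequencing at a shallower depth at the count level: each read
#' survives independently with probability `p = target_depth / current
#' depth`, and a molecule (UMI) is retained if at least one of its reads
#' survives. With `r` reads per molecule the survival probability is
#' `1 - (1 - p)^r`, applied as binomial thinning of the UMI counts. When
#' `reads_per_molecule` is `NULL` the UMI counts themselves are binomially
#' thinned at rate `p` (optimistic about saturation, since it ignores
#' read-level duplication).
#'
#' @param dataset a [kit_dataset()].
#' @param reads_per_molecule mean reads per molecule, a single number or a
#'   per-cell vector; `NULL` for direct UMI thinning.
#' @param target_depth desired mean reads per cell; must not exceed the
#'   current mean depth.
#' @param seed integer seed.
#' @return a [kit_dataset()] with thinned counts.
#' @export
downsample_depth <- function(dataset, reads_per_molecule, target_depth, seed) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  n_cells <- nrow(dataset$counts)
  umis_per_cell <- Matrix::rowSums(dataset$counts)
  rpm <- if (is.null(reads_per_molecule)) rep(1, n_cells) else {
    stopifnot_msg(all(reads_per_molecule >= 1),
                  "`reads_per_molecule` must be >= 1")
    rep_len(reads_per_molecule, n_cells)
  }
  current_depth <- sum(umis_per_cell * rpm) / n_cells
  stopifnot_msg(target_depth <= current_depth,
                sprintf("target_depth (%g) exceeds current mean depth (%g)",
                        target_depth, current_depth))
  p <- target_depth / current_depth
  if (p == 1) return(dataset)

  with_seed(seed, {
    m <- dataset$counts
    trip <- Matrix::summary(m) # i, j, x triplets
    surv_p <- if (is.null(reads_per_molecule)) rep(p, nrow(trip)) else {
      1 - (1 - p)^rpm[trip$i]
    }
    kept <- rbinom(nrow(trip), size = trip$x, prob = surv_p)
    thinned <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = kept,
                                    dims = dim(m), dimnames = dimnames(m))
    out <- dataset
    out$counts <- Matrix::drop0(as_sparse(thinned))
    out
  })
}

#' Saturation series: median genes and UMIs per cell across a depth grid
#'
#' For each depth on the grid the dataset is thinned with
#' [downsample_depth()] and the median per-cell gene and UMI counts are
#' recorded. The default grid runs from 2000 to 30000 reads per cell in
#' steps of 2000 (15 points, full depth included).
#'
#' @param dataset a [kit_dataset()].
#' @param reads_per_molecule as in [downsample_depth()].
#' @param depth_grid increasing vector of reads-per-cell depths.
#' @param seed integer seed.
#' @return object of class `saturation_series`: data.frame-backed list with
#'   `kit_id`, `depths`, `median_genes`, `median_umis`.
#' @export
saturation_series <- function(dataset, reads_per_molecule = NULL,
                              depth_grid = seq(2000, 30000, by = 2000),
                              seed = 1) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  stopifnot_msg(nrow(dataset$counts) > 0 && sum(dataset$counts) > 0,
                "empty dataset")
  stopifnot_msg(length(depth_grid) >= 1 && all(diff(depth_grid) > 0),
                "`depth_grid` must be strictly increasing")
  res <- vapply(seq_along(depth_grid), function(k) {
    ds <- downsample_depth(dataset, reads_per_molecule, depth_grid[k],
                           seed = seed + k)
    m <- ds$counts
    c(genes = median(Matrix::rowSums(m > 0)),
      umis = median(Matrix::rowSums(m)))
  }, numeric(2))
  structure(list(kit_id = dataset$kit_id, depths = depth_grid,
                 median_genes = unname(res["genes", ]),
                 median_umis = unname(res["umis", ])),
            class = "saturation_series")
}

#' @export
print.saturation_series <- function(x, ...) {
  cat("<saturation_series> ", x$kit_id, ": ", length(x$depths),
      " depths [", min(x$depths), ", ", max(x$depths), "]\n", sep = "")
  print(data.frame(depth = x$depths, median_genes = x$median_genes,
                   median_umis = x$median_umis), row.names = FALSE)
  invisible(x)
}

#' Fit a Michaelis-Menten saturation curve to a depth series
#'
#' Least-squares fit of `nu = Vmax * S / (Km + S)` where `nu` is the median
#' gene or UMI count per cell and `S` the read depth per cell. `Vmax` is the
#' saturation level and `Km` the depth of half-maximal detection.
#' Initialization: `Vmax0 =` maximal observed `nu`, `Km0 =` median depth.
#'
#' @param series a [saturation_series()], or a list with `depths` and the
#'   metric vector.
#' @param metric `"genes"` or `"umis"`.
#' @return object of class `mm_fit` with `vmax`, `km`, `metric`,
#'   `residual_norm`, and the data it was fitted to. Supports [coef()],
#'   [predict()] (argument `newdepth`) and [print()].
#' @export
fit_mm <- function(series, metric = c("genes", "umis")) {
  metric <- match.arg(metric)
  S <- series$depths
  nu <- switch(metric, genes = series$median_genes, umis = series$median_umis)
  stopifnot_msg(length(S) >= 3, "need >= 3 depth points")
  stopifnot_msg(any(nu > 0), "degenerate (all-zero) series")
  start <- c(vmax = max(nu), km = median(S))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) nu - p[["vmax"]] * S / (p[["km"]] + S),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- fit$par
  resid <- nu - cf[["vmax"]] * S / (cf[["km"]] + S)
  structure(list(metric = metric, vmax = cf[["vmax"]], km = cf[["km"]],
                 residual_norm = sqrt(sum(resid^2)),
                 depths = S, observed = nu,
                 kit_id = if (!is.null(series$kit_id)) series$kit_id else NA_character_),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> ", x$metric, " saturation",
      if (!is.na(x$kit_id)) paste0(" (", x$kit_id, ")"), "\n", sep = "")
  cat("  Vmax = ", signif(x$vmax, 6), ", Km = ", signif(x$km, 6),
      " reads/cell, residual norm = ", signif(x$residual_norm, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
predict.mm_fit <- function(object, newdepth = object$depths, ...) {
  object$vmax * newdepth / (object$km + newdepth)
}

#' Sensitivity tiers from clustered saturation curves
#'
#' Evaluates each kit's fitted curve at `n_points` equidistant depths
#' spanning the common depth range, Ward-clusters the resulting vectors
#' (Euclidean distance) and cuts the tree at `k` tiers. Tiers are numbered
#' by descending mean curve value, so tier 1 is the most sensitive group.
#'
#' @param fits named list of [fit_mm()] objects, one per kit (names used as
#'   kit ids when present).
#' @param k number of tiers.
#' @param n_points number of equidistant curve evaluations (default 34).
#' @return named integer vector: kit -> tier.
#' @export
saturation_tiers <- function(fits, k, n_points = 34) {
  stopifnot_msg(length(fits) >= 2, "need >= 2 kits")
  stopifnot_msg(is_count(k) && k >= 1 && k <= length(fits),
                "`k` must be between 1 and the number of kits")
  ids <- names(fits)
  if (is.null(ids))
    ids <- vapply(fits, function(f) f$kit_id, character(1))
  lo <- max(vapply(fits, function(f) min(f$depths), numeric(1)))
  hi <- min(vapply(fits, function(f) max(f$depths), numeric(1)))
  grid <- seq(lo, hi, length.out = n_points)
  curves <- t(vapply(fits, function(f) predict(f, grid), numeric(n_points)))
  rownames(curves) <- ids
  cl <- cutree(hclust(dist(curves), method = "ward.D2"), k = k)
  means <- tapply(rowMeans(curves), cl, mean)
  rank_of <- rank(-means, ties.method = "first")
  tiers <- rank_of[as.character(cl)]
  setNames(as.integer(tiers), ids)
}
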