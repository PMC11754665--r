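#' Fixed-threshold tiers for the rule-based categories
#'
#' Applies the fixed printed thresholds of the rule-based tiering
#' categories:
#' * `cell_recovery`: observed yield within +/-20% of `target` (inclusive)
#'   is Tier 1, otherwise Tier 2; `values` are called-cell counts.
#' * `max_cell_yield`: >20000 cells Tier 1; 10000-20000 Tier 2; <10000
#'   Tier 3.
#' * `protocol_time` (hours): <8.5 Tier 1 (~1 work day); 8.5-16 Tier 2;
#'   >16 Tier 3.
#' * `mt_fraction` (percent): ~0% (below `approx_zero`) Tier 1; <10%
#'   Tier 2; >10% Tier 3.
#' * `rp_fraction` (percent): ~0% Tier 1; otherwise Tier 2.
#'
#' @param values numeric vector (named per kit if desired).
#' @param category one of the five category names above.
#' @param target targeted cell count (required for `cell_recovery`).
#' @param approx_zero operational cutoff for "approximately 0%" (default
#'   0.5, in percent).
#' @return integer vector of tiers (1 = best), named like `values`.
#' @export
rule_tiers <- function(values, category = c("cell_recovery", "max_cell_yield",
                                            "protocol_time", "mt_fraction",
                                            "rp_fraction"),
                       target = NULL, approx_zero = 0.5) {
  category <- match.arg(category)
  tiers <- switch(category,
    cell_recovery = {
      stopifnot_msg(is.numeric(target) && target > 0,
                    "`target` required for cell_recovery")
      ifelse(values >= 0.8 * target & values <= 1.2 * target, 1L, 2L)
    },
    max_cell_yield = ifelse(values > 20000, 1L, ifelse(values >= 10000, 2L, 3L)),
    protocol_time = ifelse(values < 8.5, 1L, ifelse(values <= 16, 2L, 3L)),
    mt_fraction = ifelse(values < approx_zero, 1L,
                         ifelse(values <= 10, 2L, 3L)),
    rp_fraction = ifelse(values < approx_zero, 1L, 2L))
  setNames(as.integer(tiers), names(values))
}

#' Natural-break tiers from a kernel density estimate
#'
#' Fits a Gaussian KDE (Scott-rule bandwidth) to the one-dimensional
#' metric values (optionally log1p-transformed first), places tier
#' boundaries at the interior local minima of the density, and numbers the
#' groups best-first according to `higher_is_better`. With no interior
#' minimum all values share one tier.
#'
#' @param values numeric vector (>= 3 values), named per kit if desired.
#' @param higher_is_better orientation of the metric (default TRUE).
#' @param log1p_transform apply `log1p` before density estimation (the
#'   treatment used for cost-like metrics).
#' @param grid_n density grid resolution (default 512).
#' @return integer tier vector named like `values`.
#' @export
kde_break_tiers <- function(values, higher_is_better = TRUE,
                            log1p_transform = FALSE, grid_n = 512) {
  stopifnot_msg(length(values) >= 3, "need >= 3 values")
  v <- if (log1p_transform) log1p(values) else values
  if (diff(range(v)) == 0)
    return(setNames(rep(1L, length(values)), names(values)))
  bw <- bw_scott(v)
  d <- density(v, bw = bw, n = grid_n, from = min(v) - bw, to = max(v) + bw)
  y <- d$y
  interior_min <- which(diff(sign(diff(y))) == 2) + 1 # valleys of the density
  if (!length(interior_min))
    return(setNames(rep(1L, length(values)), names(values)))
  breaks <- d$x[interior_min]
  grp <- findInterval(v, breaks) + 1L # 1 = lowest-value group
  if (higher_is_better) grp <- max(grp) + 1L - grp
  # renumber contiguously from 1 in case some band is empty
  setNames(as.integer(factor(grp, levels = sort(unique(grp)))), names(values))
}

#' Tiers from Ward clustering of multi-dimensional metrics
#'
#' Ward clustering (Euclidean distance) of the kit rows of a metric matrix,
#' cut at `k` groups; tiers are numbered by the group means so tier 1 is the
#' best-performing group under the metric orientation.
#'
#' @param matrix kits x metrics numeric matrix with >= k rows.
#' @param k number of tiers.
#' @param higher_is_better orientation used to order the tiers.
#' @return integer tier vector named by the matrix rownames.
#' @export
cluster_tiers <- function(matrix, k, higher_is_better = TRUE) {
  stopifnot_msg(is.matrix(matrix) && nrow(matrix) >= k,
                "need at least k rows")
  cl <- cutree(hclust(dist(matrix), method = "ward.D2"), k = k)
  means <- tapply(rowMeans(matrix), cl, mean)
  ord <- if (higher_is_better) rank(-means, ties.method = "first") else
    rank(means, ties.method = "first")
  tiers <- ord[as.character(cl)]
  setNames(as.integer(tiers), rownames(matrix))
}

#' Metric table with per-metric orientation
#'
#' A kits x metrics matrix plus the set of metrics whose optimum is the
#' smallest value (inverted orientation). The default inverted set matches
#' the summary-figure convention: protocol time, both cost metrics,
#' mitochondrial QC, reference-composition (cophenetic) similarity and gene
#' expression stability (GD50).
#'
#' @param values kits x metrics numeric matrix with dimnames.
#' @param inverted character vector of metric names whose optimum is the
#'   minimum.
#' @return object of class `metric_table`.
#' @export
metric_table <- function(values,
                         inverted = c("Protocol Time", "Cost (Equipment)",
                                      "Cost (per Cell)", "Mito QC",
                                      "CyTOF Similarity",
                                      "Gene Expression Stability")) {
  stopifnot_msg(is.matrix(values) && !is.null(rownames(values)) &&
                  !is.null(colnames(values)),
                "`values` must be a matrix with kit rownames and metric colnames")
  structure(list(values = values,
                 inverted = intersect(inverted, colnames(values))),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table> ", nrow(x$values), " kits x ", ncol(x$values),
      " metrics (inverted: ",
      paste(x$inverted, collapse = ", "), ")\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Normalized feature scores in \[0, 1\]
#'
#' Per metric, min-max normalizes the values across kits; metrics with
#' inverted orientation report `1 -` the normalized value, so 1 is always
#' optimal. A constant metric is undefined under min-max and is set to the
#' neutral 0.5 for all kits, with a warning.
#'
#' @param table a [metric_table()] (>= 2 kits).
#' @return kits x metrics matrix of scores in \[0, 1\].
#' @export
feature_scores <- function(table) {
  stopifnot_msg(inherits(table, "metric_table"), "`table` must be a metric_table")
  v <- table$values
  stopifnot_msg(nrow(v) >= 2, "need >= 2 kits per metric")
  out <- apply(v, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) return(rep(0.5, length(col)))
    (col - rng[1]) / diff(rng)
  })
  const <- apply(v, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    warning("constant metrics set to neutral 0.5: ",
            paste(colnames(v)[const], collapse = ", "))
  for (mname in table$inverted)
    if (!const[mname]) out[, mname] <- 1 - out[, mname]
  dimnames(out) <- dimnames(v)
  out
}
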