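#' Consensus of two annotator label vectors
#'
#' Cells on which the two annotators agree keep the shared label; discordant
#' cells become `"Unassigned"`.
#'
#' @param label_a,label_b character vectors of equal length.
#' @param unassigned the label used for discordant cells.
#' @return character vector of consensus labels.
#' @export
consensus_labels <- function(label_a, label_b, unassigned = "Unassigned") {
  stopifnot_msg(length(label_a) == length(label_b),
                "label vectors must have equal length")
  ifelse(label_a == label_b, label_a, unassigned)
}

#' Majority reclassification of overclustered cells
#'
#' For each fine-grained cluster, if the modal consensus label covers at
#' least `majority_frac` of the cluster's cells and is not `"Unassigned"`,
#' all cells in the cluster receive that label; otherwise the cluster's
#' labels are left unchanged. Ties for the modal label never qualify.
#' The operation is idempotent.
#'
#' @param consensus per-cell consensus labels.
#' @param cluster_assignments per-cell cluster ids (same length).
#' @param majority_frac qualifying majority fraction (default 0.60).
#' @param unassigned the excluded majority label.
#' @return character vector of refined labels.
#' @export
overcluster_reclassify <- function(consensus, cluster_assignments,
                                   majority_frac = 0.60,
                                   unassigned = "Unassigned") {
  stopifnot_msg(length(consensus) == length(cluster_assignments),
                "labels and cluster ids must have equal length")
  stopifnot_msg(length(cluster_assignments) > 0 &&
                  !anyNA(cluster_assignments),
                "cluster ids must be present for every cell")
  refined <- consensus
  for (cl in unique(cluster_assignments)) {
    idx <- which(cluster_assignments == cl)
    tab <- sort(table(consensus[idx]), decreasing = TRUE)
    is_tie <- length(tab) > 1 && tab[1] == tab[2]
    modal <- names(tab)[1]
    if (!is_tie && modal != unassigned && tab[1] / length(idx) >= majority_frac)
      refined[idx] <- modal
  }
  refined
}

#' Bootstrapped cell-type proportions
#'
#' Each of `n_boot` draws resamples `n_sample` cells with replacement, drops
#' cells carrying excluded labels, and renormalizes the remaining label
#' proportions to 1. Returns draws, their means and percentile 95%
#' confidence intervals.
#'
#' @param labels per-cell label vector (all replicates aggregated).
#' @param n_boot number of resamples (study default 500).
#' @param n_sample cells per resample (study default 7882).
#' @param seed integer seed.
#' @param exclude labels dropped before renormalization (default
#'   Megakaryocytes and Unassigned, the labels absent from the reference).
#' @return object of class `proportion_bootstrap`: list with `draws`
#'   (n_boot x type matrix), `mean`, `ci` (type x 2), `n_boot`, `n_sample`.
#' @export
bootstrap_proportions <- function(labels, n_boot = 500, n_sample = 7882,
                                  seed = 1,
                                  exclude = c("Megakaryocytes", "Unassigned")) {
  stopifnot_msg(length(labels) > 0, "empty label vector")
  stopifnot_msg(is_count(n_sample) && n_sample > 0, "`n_sample` must be > 0")
  types <- sort(setdiff(unique(labels), exclude))
  stopifnot_msg(length(types) > 0, "no labels left after exclusion")
  draws <- with_seed(seed, {
    one <- function(i) {
      s <- labels[sample.int(length(labels), n_sample, replace = TRUE)]
      s <- s[!(s %in% exclude)]
      tab <- table(factor(s, levels = types))
      as.numeric(tab) / max(1L, length(s))
    }
    matrix(vapply(seq_len(n_boot), one, numeric(length(types))),
           nrow = n_boot, ncol = length(types), byrow = TRUE,
           dimnames = list(NULL, types))
  })
  ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(draws = draws, mean = colMeans(draws), ci = ci,
                 n_boot = n_boot, n_sample = n_sample),
            class = "proportion_bootstrap")
}

#' @export
print.proportion_bootstrap <- function(x, ...) {
  cat("<proportion_bootstrap> ", x$n_boot, " draws of ", x$n_sample,
      " cells\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Mean absolute difference of bootstrapped proportions vs a reference
#'
#' Per bootstrap draw and cell type, the absolute difference between the
#' drawn proportion and the reference proportion; summarized as the mean and
#' percentile 95% CI over draws. Types present on one side only are treated
#' as 0 on the other, with a warning.
#'
#' @param boot a [bootstrap_proportions()] result.
#' @param reference a [proportion_table()].
#' @return data.frame with columns `cell_type`, `mad`, `lower`, `upper`.
#' @export
mad_vs_reference <- function(boot, reference) {
  stopifnot_msg(inherits(boot, "proportion_bootstrap"),
                "`boot` must be a proportion_bootstrap")
  stopifnot_msg(inherits(reference, "proportion_table"),
                "`reference` must be a proportion_table")
  types <- union(colnames(boot$draws), names(reference$proportions))
  missing_any <- setdiff(types, colnames(boot$draws))
  missing_ref <- setdiff(types, names(reference$proportions))
  if (length(missing_any) || length(missing_ref))
    warning("cell types missing on one side treated as proportion 0: ",
            paste(union(missing_any, missing_ref), collapse = ", "))
  d <- matrix(0, nrow(boot$draws), length(types),
              dimnames = list(NULL, types))
  d[, colnames(boot$draws)] <- boot$draws
  ref <- setNames(rep(0, length(types)), types)
  ref[intersect(types, names(reference$proportions))] <-
    reference$proportions[intersect(types, names(reference$proportions))]
  absdiff <- abs(sweep(d, 2, ref))
  ci <- t(apply(absdiff, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  data.frame(cell_type = types, mad = colMeans(absdiff),
             lower = ci[, 1], upper = ci[, 2], row.names = NULL)
}

#' Ward dendrogram of kit compositions with a reference leaf
#'
#' Ward clustering (Euclidean distance) of the kits' mean cell-type
#' proportion vectors together with the reference distribution as an extra
#' leaf. Each kit's similarity score is its cophenetic distance to the
#' reference leaf (smaller = more similar).
#'
#' @param kit_means named list of mean-proportion vectors (one per kit), or
#'   a named list of [bootstrap_proportions()] objects.
#' @param reference a [proportion_table()].
#' @return list with `hclust` (the dendrogram), `cophenetic_to_reference`
#'   (named per-kit distances) and the assembled `matrix`.
#' @export
proportion_dendrogram <- function(kit_means, reference) {
  stopifnot_msg(length(kit_means) >= 2 && !is.null(names(kit_means)),
                "need >= 2 named kits")
  stopifnot_msg(inherits(reference, "proportion_table"),
                "`reference` must be a proportion_table")
  vecs <- lapply(kit_means, function(v) if (inherits(v, "proportion_bootstrap")) v$mean else v)
  types <- sort(Reduce(union, c(lapply(vecs, names),
                                list(names(reference$proportions)))))
  fill <- function(v) {
    out <- setNames(rep(0, length(types)), types)
    out[intersect(types, names(v))] <- v[intersect(types, names(v))]
    out
  }
  mat <- rbind(t(vapply(vecs, fill, numeric(length(types)))),
               reference = fill(reference$proportions))
  rownames(mat) <- c(names(kit_means), reference$source_id)
  hc <- hclust(dist(mat), method = "ward.D2")
  coph <- as.matrix(cophenetic(hc))
  scores <- coph[names(kit_means), reference$source_id]
  list(hclust = hc, cophenetic_to_reference = scores, matrix = mat)
}
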