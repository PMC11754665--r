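#' Run the full benchmarking pipeline on a panel of kits
#'
#' Executes every stage on each kit of a (typically simulated) panel:
#' read-utilization accounting, saturation series + Michaelis-Menten fits,
#' preprocessing and per-cell QC, paired dropout/specificity bootstrap,
#' pseudobulk + highly-deviant-gene selection, consensus annotation with
#' overcluster reclassification, bootstrapped composition scored against
#' the reference, Leiden resolution scan with partition scores, one-vs-rest
#' differential expression, and the final normalized feature-score matrix.
#'
#' Problem sizes default to desk-scale values suited to simulated panels;
#' the study-scale defaults of the individual stages are documented on each
#' function.
#'
#' @param panel named per-kit list with elements `dataset`, `reads`,
#'   `labels` (as produced by [simulate_kit_panel()]).
#' @param reference a [proportion_table()] reference composition.
#' @param target_cells targeted cell count per kit (for recovery/tiers).
#' @param depth_grid saturation depth grid.
#' @param n_boot,n_sample_stability dropout/specificity bootstrap sizes.
#' @param n_boot_comp,n_sample_comp composition bootstrap sizes.
#' @param n_hdg number of highly deviant genes for the embedding.
#' @param n_pcs PCs used for the clustering embedding.
#' @param deg_subsample cells kept for differential expression.
#' @param resolution_grid Leiden resolution grid.
#' @param seed integer seed.
#' @return list with per-kit stage results (`per_kit`), the assembled
#'   `metric_table`, `feature_scores` matrix, and `composition` (dendrogram
#'   + MADs).
#' @export
run_kit_benchmark <- function(panel, reference, target_cells = 1000,
                              depth_grid = seq(2000, 30000, by = 2000),
                              n_boot = 50, n_sample_stability = 1000,
                              n_boot_comp = 200, n_sample_comp = 1000,
                              n_hdg = 200, n_pcs = 10,
                              deg_subsample = 1000,
                              resolution_grid = seq(0.1, 1.0, by = 0.1),
                              seed = 1) {
  stopifnot_msg(length(panel) >= 2 && !is.null(names(panel)),
                "`panel` must be a named list of >= 2 kits")
  kits <- names(panel)
  per_kit <- list()
  common_genes <- Reduce(intersect, lapply(panel, function(k)
    colnames(k$dataset$counts)[Matrix::colSums(k$dataset$counts) > 0]))

  for (kid in kits) {
    k <- panel[[kid]]
    util <- read_utilization(k$reads)
    pp <- suppressWarnings(preprocess(k$dataset, n_subsample = NULL, seed = seed))
    qc <- suppressWarnings(percell_qc(pp))
    rpm <- 2
    cur_depth <- rpm * sum(pp$counts) / nrow(pp$counts)
    grid <- depth_grid[depth_grid <= cur_depth]
    stopifnot_msg(length(grid) >= 3,
                  "depth grid does not fit under the kit's sequencing depth")
    series <- saturation_series(pp, reads_per_molecule = rpm,
                                depth_grid = grid, seed = seed)
    fit_genes <- fit_mm(series, "genes")
    fit_umis <- fit_mm(series, "umis")
    stab <- bootstrap_stability(pp, n_boot = n_boot,
                                n_sample = n_sample_stability,
                                common_genes = common_genes, seed = seed)
    pb <- pseudobulk_expression(pp)

    # annotation: consensus of the two annotators, refined on an
    # overclustering of the HDG-PCA embedding
    keep <- pp$barcodes
    sel <- match(keep, k$dataset$barcodes)
    cons <- consensus_labels(k$labels$label_a[sel], k$labels$label_b[sel])
    hdg <- select_deviant_genes(pp, k = min(n_hdg, ncol(pp$counts)))
    norm <- suppressWarnings(cpm_normalize(pp$counts[, hdg, drop = FALSE]))
    emb <- prcomp(as.matrix(log1p(norm)), center = TRUE)$x
    emb <- emb[, seq_len(min(n_pcs, ncol(emb))), drop = FALSE]
    over <- leiden_clusters(emb, resolution = 2, seed = seed)
    refined <- overcluster_reclassify(cons, over)

    scan <- optimal_resolution_scan(emb, refined,
                                    resolution_grid = resolution_grid,
                                    seed = seed)
    scores <- partition_scores(scan$clusters, refined, emb)
    boot <- bootstrap_proportions(refined, n_boot = n_boot_comp,
                                  n_sample = n_sample_comp, seed = seed)
    deg <- deg_one_vs_rest(pp, labels = refined, n_subsample = deg_subsample,
                           seed = seed)

    per_kit[[kid]] <- list(
      utilization = util,
      umi_recovery = umi_recovery(sum(pp$counts), k$reads$total_reads),
      qc = qc, series = series, fit_genes = fit_genes, fit_umis = fit_umis,
      stability = stab, pseudobulk = pb, consensus = cons, refined = refined,
      partition = scores, resolution = scan$resolution, boot = boot,
      deg = deg,
      recovery = recovery_rate(nrow(pp$counts), target_cells))
  }

  dend <- proportion_dendrogram(lapply(per_kit, function(x) x$boot$mean),
                                reference)
  mads <- lapply(per_kit, function(x) mad_vs_reference(x$boot, reference))

  metrics <- do.call(rbind, lapply(kits, function(kid) {
    x <- per_kit[[kid]]
    c("Read Utilization" = unname(x$utilization["usable"]),
      "Cell Yield (% of Target)" = x$recovery,
      "Gene Saturation" = x$fit_genes$vmax,
      "UMI Saturation" = x$fit_umis$vmax,
      "Genes (per Cell)" = median(x$qc$n_genes),
      "UMIs (per Cell)" = median(x$qc$n_umis),
      "Mito QC" = median(x$qc$pct_mt),
      "Gene Expression Stability" = unname(x$stability$mean["gd50"]),
      "CyTOF Similarity" = unname(dend$cophenetic_to_reference[kid]),
      "Differential Expression" = mean(x$deg$counts),
      "Cluster Discrimination" = unname(x$partition["ari"]))
  }))
  rownames(metrics) <- kits
  mt <- metric_table(metrics)
  fs <- suppressWarnings(feature_scores(mt))

  list(per_kit = per_kit, metric_table = mt, feature_scores = fs,
       composition = list(dendrogram = dend, mads = mads))
}
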