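#' Kit profile: the generative parameters of one library-preparation kit
#'
#' Bundles the knobs that make simulated kits differ in the ways the
#' benchmarking metrics measure: capture efficiency (scales per-cell UMI
#' totals), gene/UMI saturation parameters, the exponential dropout decay
#' rate, cell-type-specific recovery bias, mitochondrial and ribosomal mass
#' fractions, the size of the ambient barcode tail, and the proportions of
#' the three read-assignment categories (A: mapped + cell barcode, B: mapped
#' + non-cell barcode, C: everything else).
#'
#' @param kit_id single string naming the kit.
#' @param capture_efficiency fraction in (0, 1]; multiplies the expected
#'   per-cell UMI total.
#' @param saturation_vmax_genes asymptotic median genes per cell.
#' @param saturation_km_reads reads per cell at half-maximal gene detection.
#' @param dropout_decay_b exponential dropout decay rate per CPM, in
#'   \[0, 0.05\].
#' @param celltype_bias named numeric vector of multiplicative recovery
#'   weights (> 0) per cell type; types absent from it default to weight 1.
#' @param mt_fraction,rp_fraction expected fraction of counts in
#'   mitochondrial / ribosomal-protein genes, each in \[0, 1).
#' @param ambient_barcode_count number of ambient (non-cell) barcodes to
#'   plant in rank profiles.
#' @param read_category_probs numeric 3-vector of category A/B/C
#'   probabilities; must sum to 1 within 1e-12.
#' @param dispersion gamma-Poisson dispersion (1/size) shared by all genes
#'   of the kit; 0 gives pure Poisson noise.
#' @return object of class `kit_profile`.
#' @export
kit_profile <- function(kit_id,
                        capture_efficiency = 1,
                        saturation_vmax_genes = 4000,
                        saturation_km_reads = 8000,
                        dropout_decay_b = 0.01,
                        celltype_bias = numeric(0),
                        mt_fraction = 0.05,
                        rp_fraction = 0.20,
                        ambient_barcode_count = 20000,
                        read_category_probs = c(0.6, 0.2, 0.2),
                        dispersion = 0.3) {
  stopifnot_msg(is.character(kit_id) && length(kit_id) == 1L,
                "`kit_id` must be a single string")
  stopifnot_msg(is_fraction(capture_efficiency) && capture_efficiency > 0,
                "`capture_efficiency` must be in (0, 1]")
  stopifnot_msg(is.numeric(dropout_decay_b) && dropout_decay_b >= 0 &&
                  dropout_decay_b <= 0.05,
                "`dropout_decay_b` must lie in [0, 0.05]")
  stopifnot_msg(all(celltype_bias > 0), "all `celltype_bias` weights must be > 0")
  stopifnot_msg(is_fraction(mt_fraction) && mt_fraction < 1,
                "`mt_fraction` must be in [0, 1)")
  stopifnot_msg(is_fraction(rp_fraction) && rp_fraction < 1,
                "`rp_fraction` must be in [0, 1)")
  stopifnot_msg(mt_fraction + rp_fraction < 1,
                "mt_fraction + rp_fraction must be < 1")
  stopifnot_msg(length(read_category_probs) == 3L &&
                  all(read_category_probs >= 0) &&
                  abs(sum(read_category_probs) - 1) <= 1e-12,
                "`read_category_probs` must be a 3-vector summing to 1")
  structure(list(
    kit_id = kit_id,
    capture_efficiency = capture_efficiency,
    saturation_vmax_genes = saturation_vmax_genes,
    saturation_km_reads = saturation_km_reads,
    dropout_decay_b = dropout_decay_b,
    celltype_bias = celltype_bias,
    mt_fraction = mt_fraction,
    rp_fraction = rp_fraction,
    ambient_barcode_count = ambient_barcode_count,
    read_category_probs = as.numeric(read_category_probs),
    dispersion = dispersion
  ), class = "kit_profile")
}

#' @export
print.kit_profile <- function(x, ...) {
  cat("<kit_profile> ", x$kit_id, "\n", sep = "")
  cat("  capture efficiency: ", x$capture_efficiency,
      ", dropout decay b: ", x$dropout_decay_b, "\n", sep = "")
  cat("  saturation Vmax (genes): ", x$saturation_vmax_genes,
      ", Km (reads/cell): ", x$saturation_km_reads, "\n", sep = "")
  cat("  read category probs (A/B/C): ",
      paste(signif(x$read_category_probs, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Reference cell-type proportion table
#'
#' A named set of cell-type fractions summing to one, e.g. a cytometry-derived
#' reference distribution against which kit compositions are scored.
#'
#' @param source_id single string identifying the source of the proportions.
#' @param proportions named numeric vector of fractions; must sum to 1 within
#'   1e-9 and lie in \[0, 1\].
#' @return object of class `proportion_table`.
#' @export
proportion_table <- function(source_id, proportions) {
  stopifnot_msg(is.numeric(proportions) && !is.null(names(proportions)) &&
                  all(nzchar(names(proportions))),
                "`proportions` must be a named numeric vector")
  stopifnot_msg(all(proportions >= 0 & proportions <= 1),
                "proportions must lie in [0, 1]")
  stopifnot_msg(abs(sum(proportions) - 1) <= 1e-9,
                "proportions must sum to 1 within 1e-9")
  structure(list(source_id = source_id, proportions = proportions),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("<proportion_table> source:", x$source_id, "\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Container for one kit/replicate dataset
#'
#' Holds a sparse cells x genes UMI count matrix together with barcode and
#' gene metadata, and optionally per-cell truth labels and doublet scores.
#' All generators and pipeline stages produce and consume this class.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (coerced to sparse).
#' @param barcodes character vector of unique cell barcodes (rownames).
#' @param genes data.frame with columns `symbol`, `length_bp`, `gc_fraction`,
#'   `is_mt`, `is_rp`; one row per gene.
#' @param kit_id,replicate_id identifiers.
#' @param cell_labels optional per-cell cell-type labels.
#' @param doublet_scores optional per-cell doublet scores in \[0, 1\].
#' @return object of class `kit_dataset`.
#' @export
kit_dataset <- function(counts, barcodes, genes, kit_id, replicate_id = "rep1",
                        cell_labels = NULL, doublet_scores = NULL) {
  counts <- as_sparse(counts)
  stopifnot_msg(length(barcodes) == nrow(counts), "one barcode per row required")
  stopifnot_msg(!anyDuplicated(barcodes), "barcodes must be unique")
  stopifnot_msg(nrow(genes) == ncol(counts), "one gene record per column required")
  stopifnot_msg(all(counts@x >= 0) && all(counts@x == floor(counts@x)),
                "counts must be non-negative integers")
  if (!is.null(cell_labels))
    stopifnot_msg(length(cell_labels) == nrow(counts),
                  "cell_labels length must equal the cell count")
  if (!is.null(doublet_scores))
    stopifnot_msg(length(doublet_scores) == nrow(counts) &&
                    all(doublet_scores >= 0 & doublet_scores <= 1),
                  "doublet_scores must be per-cell fractions in [0, 1]")
  rownames(counts) <- barcodes
  colnames(counts) <- genes$symbol
  structure(list(counts = counts, barcodes = barcodes, genes = genes,
                 kit_id = kit_id, replicate_id = replicate_id,
                 cell_labels = cell_labels, doublet_scores = doublet_scores),
            class = "kit_dataset")
}

#' @export
print.kit_dataset <- function(x, ...) {
  cat("<kit_dataset> ", x$kit_id, "/", x$replicate_id, ": ",
      nrow(x$counts), " cells x ", ncol(x$counts), " genes, ",
      sum(x$counts), " UMIs\n", sep = "")
  if (!is.null(x$cell_labels))
    cat("  labels: ", paste(head(sort(unique(x$cell_labels)), 8), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.kit_dataset <- function(x) dim(x$counts)

# internal: build the shared gene panel (symbols, lengths, GC, MT/RP flags)
make_gene_panel <- function(n_genes, mt_frac_genes = 0.013, rp_frac_genes = 0.05) {
  n_mt <- max(1L, round(n_genes * mt_frac_genes))
  n_rp <- max(1L, round(n_genes * rp_frac_genes))
  n_other <- n_genes - n_mt - n_rp
  stopifnot_msg(n_other > 0, "n_genes too small for the MT/RP panel")
  symbol <- c(sprintf("MT-G%04d", seq_len(n_mt)),
              sprintf("RP%s%04d", rep(c("S", "L"), length.out = n_rp), seq_len(n_rp)),
              sprintf("GENE%05d", seq_len(n_other)))
  data.frame(
    symbol = symbol,
    length_bp = round(exp(rnorm(n_genes, mean = log(2500), sd = 0.6))),
    gc_fraction = pmin(0.8, pmax(0.25, rnorm(n_genes, 0.45, 0.07))),
    is_mt = c(rep(TRUE, n_mt), rep(FALSE, n_rp + n_other)),
    is_rp = c(rep(FALSE, n_mt), rep(TRUE, n_rp), rep(FALSE, n_other)),
    stringsAsFactors = FALSE
  )
}

# internal: log-normal base expression plus per-type marker boosts, shared
# across kits so cross-kit pseudobulk agreement is high by construction
make_celltype_profiles <- function(genes, cell_types, marker_frac = 0.04,
                                   marker_boost = 8) {
  n_genes <- nrow(genes)
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  prof <- matrix(rep(base, length(cell_types)), ncol = length(cell_types),
                 dimnames = list(genes$symbol, cell_types))
  n_mark <- max(2L, round(n_genes * marker_frac))
  eligible <- which(!genes$is_mt & !genes$is_rp)
  for (ct in cell_types) {
    idx <- sample(eligible, n_mark)
    prof[idx, ct] <- prof[idx, ct] * marker_boost
  }
  prof
}

# internal: renormalize a probability vector so MT genes carry mt_frac,
# RP genes rp_frac, and the rest 1 - mt_frac - rp_frac
apportion_mass <- function(p, genes, mt_frac, rp_frac) {
  out <- p
  for (grp in list(list(sel = genes$is_mt, target = mt_frac),
                   list(sel = genes$is_rp, target = rp_frac),
                   list(sel = !genes$is_mt & !genes$is_rp,
                        target = 1 - mt_frac - rp_frac))) {
    s <- sum(p[grp$sel])
    out[grp$sel] <- if (s > 0) p[grp$sel] / s * grp$target else 0
  }
  out / sum(out)
}

#' Simulate a UMI count matrix for one kit
#'
#' Cells are drawn from `celltype_props` reweighted by the kit's
#' `celltype_bias` (then renormalized); each cell's expected UMI total is
#' `mean_umis_per_cell * capture_efficiency`; gene counts follow a
#' gamma-Poisson with cell-type-specific mean profiles, with mitochondrial
#' and ribosomal gene mass matching the kit's `mt_fraction` / `rp_fraction`
#' in expectation. Deterministic for a fixed seed.
#'
#' @param profile a [kit_profile()].
#' @param celltype_props a [proportion_table()] of true cell-type fractions.
#' @param n_cells,n_genes dimensions of the simulated matrix.
#' @param seed integer seed.
#' @param mean_umis_per_cell expected UMI total of a cell at capture
#'   efficiency 1. The default (`NULL`) derives it from the profile's
#'   dropout decay rate as `1e6 * dropout_decay_b`: under Poisson noise a
#'   cell library of `L` UMIs yields dropout `exp(-(L/1e6) * CPM)`, so at
#'   full capture the realized per-CPM decay rate matches
#'   `dropout_decay_b` (and scales with capture efficiency below 1).
#' @param replicate_id replicate identifier stored on the dataset.
#' @param celltype_profiles optional gene x cell-type mean-expression matrix
#'   (from an internal shared panel when omitted); pass the same matrix to
#'   several kits to make their pseudobulk profiles agree.
#' @param genes optional gene metadata data.frame matching
#'   `celltype_profiles`; generated when omitted.
#' @param doublet_rate fraction of cells given a high doublet score.
#' @return a [kit_dataset()] with truth labels and doublet scores attached.
#' @export
simulate_counts <- function(profile, celltype_props, n_cells, n_genes,
                            seed, mean_umis_per_cell = NULL,
                            replicate_id = "rep1",
                            celltype_profiles = NULL, genes = NULL,
                            doublet_rate = 0.02) {
  stopifnot_msg(inherits(profile, "kit_profile"), "`profile` must be a kit_profile")
  stopifnot_msg(inherits(celltype_props, "proportion_table"),
                "`celltype_props` must be a proportion_table")
  stopifnot_msg(is_count(n_cells) && n_cells > 0, "`n_cells` must be a positive count")
  stopifnot_msg(is_count(n_genes) && n_genes > 0, "`n_genes` must be a positive count")
  if (is.null(mean_umis_per_cell))
    mean_umis_per_cell <- 1e6 * profile$dropout_decay_b

  with_seed(seed, {
    if (is.null(genes)) genes <- make_gene_panel(n_genes)
    cell_types <- names(celltype_props$proportions)
    if (is.null(celltype_profiles))
      celltype_profiles <- make_celltype_profiles(genes, cell_types)
    stopifnot_msg(nrow(celltype_profiles) == n_genes,
                  "`celltype_profiles` must have n_genes rows")

    # kit-biased sampling of cell types
    bias <- rep(1, length(cell_types))
    names(bias) <- cell_types
    known <- intersect(names(profile$celltype_bias), cell_types)
    bias[known] <- profile$celltype_bias[known]
    w <- celltype_props$proportions * bias
    w <- w / sum(w)
    labels <- sample(cell_types, n_cells, replace = TRUE, prob = w)

    # per-gene sampling probabilities per type, MT/RP mass imposed
    probs <- vapply(cell_types, function(ct) {
      apportion_mass(celltype_profiles[, ct] / sum(celltype_profiles[, ct]),
                     genes, profile$mt_fraction, profile$rp_fraction)
    }, numeric(n_genes))

    lib <- rpois(n_cells, mean_umis_per_cell * profile$capture_efficiency)
    disp <- profile$dispersion
    counts <- matrix(0L, n_cells, n_genes)
    for (ct in cell_types) {
      idx <- which(labels == ct)
      if (!length(idx)) next
      mu <- outer(lib[idx], probs[, ct]) # cells x genes expected counts
      if (disp > 0) {
        g <- matrix(rgamma(length(mu), shape = 1 / disp, scale = disp),
                    nrow = length(idx))
        mu <- mu * g
      }
      counts[idx, ] <- matrix(rpois(length(mu), mu), nrow = length(idx))
    }

    barcodes <- sprintf("%s-BC%06d", profile$kit_id, seq_len(n_cells))
    dscore <- runif(n_cells, 0, 0.2)
    n_dbl <- round(doublet_rate * n_cells)
    if (n_dbl > 0) dscore[sample(n_cells, n_dbl)] <- runif(n_dbl, 0.3, 0.9)

    kit_dataset(counts, barcodes, genes, profile$kit_id, replicate_id,
                cell_labels = labels, doublet_scores = dscore)
  })
}

#' Simulate an aggregated read-assignment table
#'
#' Multinomial draw of `total_reads` over the three read categories with the
#' kit's category probabilities.
#'
#' @param profile a [kit_profile()].
#' @param total_reads positive count of sequenced reads.
#' @param seed integer seed.
#' @param replicate_id replicate identifier.
#' @return a [read_assignment_table()].
#' @export
simulate_read_assignments <- function(profile, total_reads, seed,
                                      replicate_id = "rep1") {
  stopifnot_msg(inherits(profile, "kit_profile"), "`profile` must be a kit_profile")
  stopifnot_msg(is_count(total_reads) && total_reads > 0,
                "`total_reads` must be a positive count")
  with_seed(seed, {
    n <- as.vector(rmultinom(1, total_reads, profile$read_category_probs))
    read_assignment_table(profile$kit_id, replicate_id, n[1], n[2], n[3])
  })
}

#' Simulate a pair of annotator label vectors
#'
#' Annotator 1 reproduces the dataset's truth labels with a small uniform
#' error; annotator 2 agrees with annotator 1 for an expected fraction
#' `agreement_rate` of cells and otherwise reports a different label.
#'
#' @param dataset a [kit_dataset()] carrying `cell_labels`.
#' @param agreement_rate expected agreement fraction between the two
#'   annotators, in \[0, 1\].
#' @param seed integer seed.
#' @param annotator1_error error rate of annotator 1 against truth.
#' @return list with character vectors `label_a` and `label_b`.
#' @export
simulate_label_pair <- function(dataset, agreement_rate, seed,
                                annotator1_error = 0.02) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  stopifnot_msg(!is.null(dataset$cell_labels),
                "dataset has no truth labels; simulate with cell labels first")
  stopifnot_msg(is_fraction(agreement_rate), "`agreement_rate` must be in [0, 1]")
  truth <- dataset$cell_labels
  alphabet <- sort(unique(truth))
  stopifnot_msg(length(alphabet) >= 2 || agreement_rate == 1,
                "label alphabet must have >= 2 labels to disagree")
  other <- function(lab) {
    pool <- setdiff(alphabet, lab)
    pool[sample.int(length(pool), 1L)]
  }
  with_seed(seed, {
    n <- length(truth)
    a <- truth
    flip <- runif(n) < annotator1_error
    a[flip] <- vapply(a[flip], other, character(1))
    b <- a
    disagree <- runif(n) >= agreement_rate
    b[disagree] <- vapply(a[disagree], other, character(1))
    list(label_a = a, label_b = b)
  })
}

#' Simulate a barcode rank profile with an ambient tail
#'
#' Log-normal UMI counts per barcode from two populations: real cells at
#' `real_umi_scale` and ambient barcodes at the much lower
#' `ambient_umi_scale`, giving the ranked profile its knee.
#'
#' @param n_real_cells,n_ambient barcode counts of the two populations.
#' @param real_umi_scale,ambient_umi_scale median UMI counts; the real scale
#'   must exceed the ambient scale.
#' @param seed integer seed.
#' @param sdlog log-scale standard deviation of each population.
#' @return a [barcode_rank_profile()].
#' @export
simulate_rank_profile <- function(n_real_cells, n_ambient, real_umi_scale,
                                  ambient_umi_scale, seed, sdlog = 0.25) {
  stopifnot_msg(is_count(n_real_cells) && n_real_cells > 0,
                "`n_real_cells` must be a positive count")
  stopifnot_msg(is_count(n_ambient), "`n_ambient` must be a count")
  stopifnot_msg(real_umi_scale > ambient_umi_scale,
                "`real_umi_scale` must exceed `ambient_umi_scale`")
  with_seed(seed, {
    counts <- c(rlnorm(n_real_cells, log(real_umi_scale), sdlog),
                if (n_ambient > 0) rlnorm(n_ambient, log(ambient_umi_scale), sdlog))
    counts <- pmax(1, round(counts))
    barcodes <- sprintf("BC%07d", seq_along(counts))
    barcode_rank_profile(setNames(counts, barcodes))
  })
}

#' Simulate a panel of kits sharing one gene panel and cell-type profiles
#'
#' Convenience wrapper used by the end-to-end pipeline: draws the gene panel
#' and cell-type expression profiles once, then simulates each kit's counts,
#' read assignments and annotator labels from its own profile.
#'
#' @param profiles list of [kit_profile()] objects.
#' @param celltype_props a [proportion_table()].
#' @param n_cells,n_genes per-kit dimensions.
#' @param seed integer seed.
#' @param total_reads reads sequenced per kit (for read accounting); the
#'   default (`NULL`) derives it per kit from the simulated library as
#'   `reads_per_molecule` times the UMI total divided by the kit's
#'   category-A probability, so UMI recovery and read utilization cohere.
#' @param reads_per_molecule mean sequenced reads per captured molecule
#'   used when deriving `total_reads`.
#' @param agreement_rate annotator agreement rate passed to
#'   [simulate_label_pair()].
#' @param mean_umis_per_cell expected per-cell UMI total at capture 1.
#' @return named list per kit with elements `dataset`, `reads`, `labels`.
#' @export
simulate_kit_panel <- function(profiles, celltype_props, n_cells, n_genes,
                               seed, total_reads = NULL, agreement_rate = 0.9,
                               mean_umis_per_cell = NULL, reads_per_molecule = 2) {
  shared <- with_seed(seed, {
    genes <- make_gene_panel(n_genes)
    list(genes = genes,
         profiles = make_celltype_profiles(genes, names(celltype_props$proportions)))
  })
  out <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ds <- simulate_counts(p, celltype_props, n_cells, n_genes,
                          seed = seed + i,
                          mean_umis_per_cell = mean_umis_per_cell,
                          celltype_profiles = shared$profiles,
                          genes = shared$genes)
    reads <- if (is.null(total_reads)) {
      round(reads_per_molecule * sum(ds$counts) / p$read_category_probs[1])
    } else total_reads
    rd <- simulate_read_assignments(p, reads, seed = seed + 100 + i)
    lp <- simulate_label_pair(ds, agreement_rate, seed = seed + 200 + i)
    out[[p$kit_id]] <- list(dataset = ds, reads = rd, labels = lp)
  }
  out
}
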