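#' Write a kit dataset as Matrix-Market with companion tables
#'
#' Writes the 10x-style triplet layout: `matrix.mtx` (genes as rows,
#' transposed from the in-memory cells x genes orientation), `barcodes.tsv`,
#' `features.tsv` (symbol, length_bp, gc_fraction, is_mt, is_rp), an
#' optional `labels.tsv`, and a `meta.json` sidecar recording kit,
#' replicate and matrix orientation.
#'
#' @param dataset a [kit_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_kit_dataset <- function(dataset, dir) {
  stopifnot_msg(inherits(dataset, "kit_dataset"), "`dataset` must be a kit_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as_sparse(Matrix::t(dataset$counts)),
                  file.path(dir, "matrix.mtx"))
  writeLines(dataset$barcodes, file.path(dir, "barcodes.tsv"))
  write.table(dataset$genes, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$cell_labels) || !is.null(dataset$doublet_scores)) {
    lab <- data.frame(barcode = dataset$barcodes)
    if (!is.null(dataset$cell_labels)) lab$cell_label <- dataset$cell_labels
    if (!is.null(dataset$doublet_scores)) lab$doublet_score <- dataset$doublet_scores
    write.table(lab, file.path(dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(kit_id = dataset$kit_id, replicate_id = dataset$replicate_id,
               orientation = "genes_x_cells")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a kit dataset written by [write_kit_dataset()]
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, optional `labels.tsv`, and `meta.json`.
#' @return a [kit_dataset()].
#' @export
read_kit_dataset <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (identical(meta$orientation, "genes_x_cells")) m <- Matrix::t(m)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- read.delim(file.path(dir, "features.tsv"), stringsAsFactors = FALSE)
  labels <- NULL; dscore <- NULL
  labfile <- file.path(dir, "labels.tsv")
  if (file.exists(labfile)) {
    lab <- read.delim(labfile, stringsAsFactors = FALSE)
    if ("cell_label" %in% names(lab)) labels <- lab$cell_label
    if ("doublet_score" %in% names(lab)) dscore <- lab$doublet_score
  }
  kit_dataset(m, barcodes, genes, meta$kit_id, meta$replicate_id,
              cell_labels = labels, doublet_scores = dscore)
}

#' Write / read read-assignment tables as TSV
#'
#' Columns: `kit_id`, `replicate_id`, `n_category_a`, `n_category_b`,
#' `n_category_c`, `total_reads`. Category conservation (A + B + C = total)
#' is validated on read.
#'
#' @param tables a [read_assignment_table()] or list of them.
#' @param path TSV file path.
#' @return `path` invisibly (write); list of tables (read).
#' @export
write_read_assignments <- function(tables, path) {
  if (inherits(tables, "read_assignment_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(kit_id = t$kit_id, replicate_id = t$replicate_id,
               n_category_a = t$n_category_a, n_category_b = t$n_category_b,
               n_category_c = t$n_category_c, total_reads = t$total_reads)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_assignments
#' @export
read_read_assignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    read_assignment_table(df$kit_id[i], df$replicate_id[i],
                          df$n_category_a[i], df$n_category_b[i],
                          df$n_category_c[i], df$total_reads[i]))
}

#' Write / read a barcode rank profile as two-column TSV
#'
#' Columns: `barcode`, `umi_count`.
#'
#' @param profile a [barcode_rank_profile()].
#' @param path TSV file path.
#' @return `path` invisibly (write); a profile (read).
#' @export
write_rank_profile <- function(profile, path) {
  stopifnot_msg(inherits(profile, "barcode_rank_profile"),
                "`profile` must be a barcode_rank_profile")
  write.table(data.frame(barcode = names(profile$counts),
                         umi_count = unname(profile$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rank_profile
#' @export
read_rank_profile <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  barcode_rank_profile(setNames(df$umi_count, df$barcode))
}

#' Read / write a reference proportion table as CSV
#'
#' Columns: `cell_type`, `proportion`; the source id is stored in a comment
#' on the first line (`# source: <id>`).
#'
#' @param table a [proportion_table()].
#' @param path CSV file path.
#' @return `path` invisibly (write); a [proportion_table()] (read).
#' @export
write_proportion_table <- function(table, path) {
  stopifnot_msg(inherits(table, "proportion_table"),
                "`table` must be a proportion_table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# source: ", table$source_id), con)
  write.table(data.frame(cell_type = names(table$proportions),
                         proportion = unname(table$proportions)),
              con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportion_table
#' @export
read_proportion_table <- function(path) {
  first <- readLines(path, n = 1)
  source_id <- sub("^# source:\\s*", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  proportion_table(source_id, setNames(df$proportion, df$cell_type))
}
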