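make_qc_dataset <- function(counts, scores = NULL, labels = NULL) {
  n <- nrow(counts)
  genes <- data.frame(symbol = colnames(counts),
                      length_bp = 1000, gc_fraction = 0.5,
                      is_mt = startsWith(colnames(counts), "MT-"),
                      is_rp = startsWith(colnames(counts), "RP"))
  kit_dataset(counts, sprintf("bc%03d", seq_len(n)), genes, "k",
              cell_labels = labels, doublet_scores = scores)
}

test_that("preprocessing applies its boundary rules exactly", {
  # cell 1: 4 genes (dropped); cell 2: 5 genes (kept)
  m <- rbind(c(1, 1, 1, 1, 0, 0),
             c(1, 1, 1, 1, 1, 0),
             matrix(2, 6, 6))
  colnames(m) <- paste0("g", 1:6)
  ds <- make_qc_dataset(m)
  out <- preprocess(ds, min_genes = 5, doublet_threshold = NULL,
                    n_subsample = NULL, min_cells_per_gene = 0)
  expect_false("bc001" %in% out$barcodes)
  expect_true("bc002" %in% out$barcodes)

  # doublet boundary: 0.25 dropped (inclusive), 0.249 kept
  m2 <- matrix(1, 4, 6, dimnames = list(NULL, paste0("g", 1:6)))
  ds2 <- make_qc_dataset(m2, scores = c(0.25, 0.249, 0.1, 0.9))
  out2 <- preprocess(ds2, min_genes = 1, n_subsample = NULL,
                     min_cells_per_gene = 0)
  expect_setequal(out2$barcodes, c("bc002", "bc003"))

  # gene prevalence boundary: 2 cells dropped, 3 cells kept
  m3 <- rbind(c(1, 1, 5), c(1, 1, 5), c(0, 1, 5), c(0, 0, 5))
  colnames(m3) <- c("gA", "gB", "gC")
  out3 <- preprocess(make_qc_dataset(m3), min_genes = 1,
                     doublet_threshold = NULL, n_subsample = NULL,
                     min_cells_per_gene = 3)
  expect_setequal(colnames(out3$counts), c("gB", "gC"))
})

test_that("preprocessing order is cells -> doublets -> subsample -> genes", {
  # a fixture whose intermediate shapes pin the order: gene gRare appears in
  # 3 cells, two of which fail earlier filters, so it must be dropped only
  # if gene filtering runs AFTER the cell filters
  m <- rbind(
    c(1, 0, 0, 0, 0, 1), # fails min_genes (2 genes < 5)... kept fields below
    c(1, 1, 1, 1, 1, 1), # doublet
    c(1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 1, 0),
    c(1, 1, 1, 1, 1, 0))
  colnames(m) <- c(paste0("g", 1:5), "gRare")
  ds <- make_qc_dataset(m, scores = c(0.1, 0.9, 0.1, 0.1, 0.1))
  out <- preprocess(ds, min_genes = 5, doublet_threshold = 0.25,
                    n_subsample = NULL, min_cells_per_gene = 2)
  # cells: bc001 dropped by min_genes, bc002 by doublet -> 3 cells remain;
  # gRare then appears in only 1 remaining cell -> dropped
  expect_equal(nrow(out$counts), 3)
  expect_false("gRare" %in% colnames(out$counts))

  # same fixture, gene filter first would have kept gRare (3 cells >= 2)
  gene_first <- Matrix::colSums(ds$counts > 0) >= 2
  expect_true(gene_first[["gRare"]])
})

test_that("subsampling is seeded, size-exact, and exempts small datasets", {
  m <- matrix(rpois(200 * 10, 3), 200, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  ds <- make_qc_dataset(m)
  a <- preprocess(ds, min_genes = 1, doublet_threshold = NULL,
                  n_subsample = 50, min_cells_per_gene = 0, seed = 3)
  b <- preprocess(ds, min_genes = 1, doublet_threshold = NULL,
                  n_subsample = 50, min_cells_per_gene = 0, seed = 3)
  expect_equal(nrow(a$counts), 50)
  expect_identical(a$barcodes, b$barcodes)
  expect_false(isTRUE(attr(a, "subsample_exempt")))

  expect_warning(
    small <- preprocess(ds, min_genes = 1, doublet_threshold = NULL,
                        n_subsample = 500, min_cells_per_gene = 0),
    "keeping all")
  expect_true(attr(small, "subsample_exempt"))
  expect_equal(nrow(small$counts), 200)
})

test_that("per-cell QC percentages match a brute-force recount", {
  m <- rbind(c(10, 40, 30, 20),  # MT share 10/100
             c(0, 5, 5, 0),
             c(3, 3, 3, 1))
  colnames(m) <- c("MT-X", "RPS1", "RPL2", "gZ")
  qc <- percell_qc(make_qc_dataset(m))
  expect_equal(qc$pct_mt[1], 10)
  expect_equal(qc$pct_rp[1], 70)
  for (i in 1:3) {
    expect_equal(qc$n_genes[i], sum(m[i, ] > 0))
    expect_equal(qc$n_umis[i], sum(m[i, ]))
    expect_equal(qc$pct_mt[i], unname(100 * m[i, 1] / sum(m[i, ])))
    expect_equal(qc$pct_rp[i], 100 * sum(m[i, 2:3]) / sum(m[i, ]))
  }
  expect_true(all(qc$pct_mt + qc$pct_rp <= 100))
  expect_true(all(qc$n_genes <= qc$n_umis))
})

test_that("a panel without MT genes yields zero mitochondrial percentages", {
  m <- matrix(5, 4, 3, dimnames = list(NULL, c("gA", "gB", "RPS9")))
  qc <- percell_qc(make_qc_dataset(m))
  expect_equal(qc$pct_mt, rep(0, 4))
})

test_that("zero-total cells get percentage 0 with a warning", {
  m <- rbind(c(2, 3), c(0, 0))
  colnames(m) <- c("MT-1", "g1")
  expect_warning(qc <- percell_qc(make_qc_dataset(m)), "zero total")
  expect_equal(qc$pct_mt[2], 0)
})

test_that("cross-kit tests hold their level under the null", {
  set.seed(5)
  cover <- mean(vapply(1:100, function(i) {
    v <- list(a = rnorm(500), b = rnorm(500), c = rnorm(500))
    compare_kits(v)$omnibus_p > 0.05
  }, logical(1)))
  expect_gte(cover, 0.90)
})

test_that("a 2-SD shift is detected by all pairwise comparisons", {
  set.seed(6)
  v <- list(a = rnorm(500), b = rnorm(500), c = rnorm(500, mean = 2))
  res <- compare_kits(v)
  expect_lt(res$omnibus_p, 0.001)
  with_c <- res$pairwise$group_a == "c" | res$pairwise$group_b == "c"
  expect_true(all(res$pairwise$p_adj[with_c] < 0.01))
})

test_that("two groups reduce to a single unadjusted Dunn comparison", {
  set.seed(7)
  v <- list(a = rnorm(100), b = rnorm(100, 0.5))
  res <- compare_kits(v)
  expect_equal(nrow(res$pairwise), 1)
  expect_equal(res$pairwise$p_adj, res$pairwise$p_raw) # Bonferroni factor 1
  expect_error(compare_kits(list(a = 1, b = rnorm(5))), ">= 2 observations")
})
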