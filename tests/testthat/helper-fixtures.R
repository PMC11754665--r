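# Shared fixture builders. Everything is generated in code at test time.

two_type_props <- function() proportion_table("truth", c(A = 0.6, B = 0.4))

pbmc_like_props <- function() {
  proportion_table("CyTOF", c(
    "B cells" = 0.12, "CD14+ monocytes" = 0.25, "CD4+ T cells" = 0.35,
    "NK cells" = 0.15, "CD8+ T cells" = 0.13))
}

# a small dataset with Poisson noise whose per-CPM dropout decay rate is
# (close to) the profile's dropout_decay_b
poisson_kit <- function(b = 0.02, n_cells = 400, n_genes = 300, seed = 42,
                        kit_id = "pois") {
  p <- kit_profile(kit_id, capture_efficiency = 1, dropout_decay_b = b,
                   dispersion = 0)
  simulate_counts(p, two_type_props(), n_cells, n_genes, seed = seed)
}

# deterministic tiny count matrix for hand-checked oracles
toy_counts_5x3 <- function() {
  m <- matrix(c(2, 0, 1,
                4, 1, 0,
                6, 0, 3,
                8, 2, 0,
                10, 1, 1), nrow = 5, byrow = TRUE)
  rownames(m) <- paste0("c", 1:5)
  colnames(m) <- paste0("g", 1:3)
  m
}

# well-separated Gaussian blobs with labels
make_blobs <- function(n_per = 100, centers = rbind(c(0, 0), c(6, 0),
                                                    c(0, 6), c(6, 6)),
                       seed = 1) {
  set.seed(seed)
  emb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1]), rnorm(n_per, centers[i, 2]))))
  list(embedding = emb, labels = rep(letters[seq_len(nrow(centers))],
                                     each = n_per))
}

good_bad_profiles <- function() {
  list(
    good = kit_profile("good", capture_efficiency = 0.9,
                       dropout_decay_b = 0.012, mt_fraction = 0.02,
                       rp_fraction = 0.15,
                       read_category_probs = c(0.8, 0.1, 0.1),
                       dispersion = 0.2),
    bad = kit_profile("bad", capture_efficiency = 0.35,
                      dropout_decay_b = 0.008, mt_fraction = 0.12,
                      rp_fraction = 0.25,
                      read_category_probs = c(0.4, 0.25, 0.35),
                      celltype_bias = c("CD14+ monocytes" = 0.4),
                      dispersion = 0.5))
}
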