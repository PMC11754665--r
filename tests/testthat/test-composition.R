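test_that("consensus labeling keeps agreements and marks discordance", {
  expect_equal(consensus_labels(c("B", "B", "T"), c("B", "T", "T")),
               c("B", "Unassigned", "T"))
  set.seed(1)
  a <- sample(LETTERS[1:4], 500, TRUE)
  b <- sample(LETTERS[1:4], 500, TRUE)
  cons <- consensus_labels(a, b)
  expect_equal(sum(cons != "Unassigned"), sum(a == b)) # recount oracle
  expect_error(consensus_labels(c("A"), c("A", "B")), "equal length")
})

test_that("overclustering reclassification follows the 60%/Unassigned rules", {
  labels <- c(rep("B", 7), rep("T", 3),          # cluster 1: 70% B -> all B
              rep("B", 11), rep("T", 9),         # cluster 2: 55% -> unchanged
              rep("Unassigned", 8), rep("T", 2)) # cluster 3: excluded majority
  clusters <- rep(1:3, c(10, 20, 10))
  ref <- overcluster_reclassify(labels, clusters)
  expect_equal(ref[1:10], rep("B", 10))
  expect_equal(ref[11:30], labels[11:30])
  expect_equal(ref[31:40], labels[31:40])

  # exact 60% qualifies (inclusive); modal ties never reclassify
  at60 <- overcluster_reclassify(c(rep("B", 6), rep("T", 4)), rep(1, 10))
  expect_equal(at60, rep("B", 10))
  tie <- overcluster_reclassify(c(rep("B", 5), rep("T", 5)), rep(1, 10))
  expect_equal(tie, c(rep("B", 5), rep("T", 5)))
})

test_that("reclassification is idempotent and only edits qualifying clusters", {
  set.seed(2)
  labels <- sample(c("B", "T", "NK", "Unassigned"), 300, TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.1))
  clusters <- sample(1:12, 300, TRUE)
  once <- overcluster_reclassify(labels, clusters)
  twice <- overcluster_reclassify(once, clusters)
  expect_identical(once, twice)

  changed <- which(once != labels)
  for (cl in unique(clusters[changed])) {
    idx <- clusters == cl
    tab <- sort(table(labels[idx]), decreasing = TRUE)
    expect_gte(tab[1] / sum(idx), 0.60)
    expect_false(names(tab)[1] == "Unassigned")
  }
})

test_that("bootstrapped proportions are valid, unbiased and reproducible", {
  single <- bootstrap_proportions(rep("A", 50), n_boot = 20, n_sample = 30,
                                  seed = 1, exclude = character(0))
  expect_equal(unname(single$mean), 1)
  expect_equal(unname(diff(single$ci[1, ])), 0)

  set.seed(3)
  labels <- sample(c("A", "B"), 20000, TRUE, prob = c(0.6, 0.4))
  boot <- bootstrap_proportions(labels, n_boot = 500, n_sample = 7882,
                                seed = 4, exclude = character(0))
  expect_true(all(abs(rowSums(boot$draws) - 1) < 1e-12))
  se <- sd(boot$draws[, "A"]) # bootstrap SE
  expect_lt(abs(boot$mean[["A"]] - 0.6), 3 * (se + sqrt(0.24 / 20000)))

  again <- bootstrap_proportions(labels, n_boot = 500, n_sample = 7882,
                                 seed = 4, exclude = character(0))
  expect_identical(boot$draws, again$draws)
})

test_that("excluded labels are dropped and proportions renormalized", {
  labels <- c(rep("A", 60), rep("B", 30), rep("Megakaryocytes", 5),
              rep("Unassigned", 5))
  boot <- bootstrap_proportions(labels, n_boot = 50, n_sample = 80, seed = 5)
  expect_setequal(colnames(boot$draws), c("A", "B"))
  expect_true(all(abs(rowSums(boot$draws) - 1) < 1e-12))
  expect_lt(abs(boot$mean[["A"]] - 60 / 90), 0.05)
})

test_that("bootstrap means converge to plug-in proportions", {
  set.seed(6)
  labels <- sample(c("A", "B", "C"), 3000, TRUE, prob = c(0.5, 0.3, 0.2))
  plugin <- as.numeric(table(factor(labels, levels = c("A", "B", "C")))) / 3000
  boot <- bootstrap_proportions(labels, n_boot = 5000, n_sample = 3000,
                                seed = 7, exclude = character(0))
  expect_true(all(abs(boot$mean - plugin) < 1e-3 + 3 * sqrt(0.25 / 3000 / sqrt(5000))))
  expect_lt(max(abs(boot$mean - plugin)), 1.5e-3)
})

test_that("MAD against a matching reference reflects only sampling noise", {
  ref <- proportion_table("CyTOF", c(A = 0.6, B = 0.4))
  set.seed(8)
  labels <- sample(c("A", "B"), 50000, TRUE, prob = c(0.6, 0.4))
  boot <- bootstrap_proportions(labels, n_boot = 200, n_sample = 7882,
                                seed = 9, exclude = character(0))
  mad <- mad_vs_reference(boot, ref)
  # |p_hat - p| for a binomial proportion has mean ~ SE * sqrt(2/pi)
  se <- sqrt(0.6 * 0.4 / 7882)
  expect_lt(max(mad$mad), se * sqrt(2 / pi) + 3 * se)

  # identical constant draws -> MAD exactly 0
  const <- bootstrap_proportions(rep(c("A", "B"), c(60, 40)), n_boot = 10,
                                 n_sample = 1e5, seed = 10,
                                 exclude = character(0))
  expect_lt(max(mad_vs_reference(const, ref)$mad), 0.01)
})

test_that("a planted monocyte depletion shows up as the maximal MAD", {
  ref <- pbmc_like_props()
  p <- ref$proportions
  biased <- p * c(1, 0.25, 1, 1, 1)[match(names(p), names(p))]
  names(biased) <- names(p)
  biased["CD14+ monocytes"] <- p[["CD14+ monocytes"]] * 0.25
  biased <- biased / sum(biased)
  set.seed(11)
  labels <- sample(names(biased), 30000, TRUE, prob = biased)
  boot <- bootstrap_proportions(labels, n_boot = 100, n_sample = 7882,
                                seed = 12, exclude = character(0))
  mad <- mad_vs_reference(boot, ref)
  worst <- mad$cell_type[which.max(mad$mad)]
  expect_equal(worst, "CD14+ monocytes")
  expect_gt(max(mad$mad), 0.10)
})

test_that("the composition dendrogram scores reference similarity copheneticly", {
  ref <- proportion_table("CyTOF", c(A = 0.5, B = 0.3, C = 0.2))
  kits <- list(match_ref = c(A = 0.5, B = 0.3, C = 0.2),
               near = c(A = 0.45, B = 0.35, C = 0.2),
               far = c(A = 0.1, B = 0.1, C = 0.8))
  d <- proportion_dendrogram(kits, ref)
  sc <- d$cophenetic_to_reference
  expect_equal(unname(which.min(sc)), 1)
  expect_equal(unname(sc[["match_ref"]]), 0)

  # identical kits merge at height 0
  d2 <- proportion_dendrogram(list(k1 = kits$near, k2 = kits$near), ref)
  expect_equal(min(d2$hclust$height), 0)

  # ultrametric property of cophenetic distances
  cm <- as.matrix(stats::cophenetic(d$hclust))
  n <- nrow(cm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(cm[i, j], max(cm[i, k], cm[k, j]) + 1e-9)
})
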