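test_that("ARI and AMI are 1 on identical partitions and ~0 on random ones", {
  set.seed(1)
  a <- sample(1:6, 10000, TRUE)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_mutual_info(a, a), 1)

  b <- sample(1:6, 10000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.01)
  expect_lt(abs(adjusted_mutual_info(a, b)), 0.01)
})

test_that("ARI matches the independent package oracle", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:10) {
    a <- sample(1:4, 300, TRUE)
    b <- a
    flip <- sample(300, 60)
    b[flip] <- sample(1:5, 60, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("agreement indices are invariant to relabeling cluster ids", {
  set.seed(3)
  labels <- sample(letters[1:4], 500, TRUE)
  clusters <- sample(1:5, 500, TRUE)
  perm <- c(3, 5, 1, 2, 4)
  relabeled <- perm[clusters]
  expect_equal(adjusted_rand_index(labels, clusters),
               adjusted_rand_index(labels, relabeled))
  expect_equal(adjusted_mutual_info(labels, clusters),
               adjusted_mutual_info(labels, relabeled))
  expect_equal(balanced_adjusted_rand_index(labels, clusters),
               balanced_adjusted_rand_index(labels, relabeled))
})

test_that("balanced indices equal plain indices for exactly equal classes", {
  set.seed(4)
  labels <- rep(LETTERS[1:4], each = 250)
  clusters <- sample(1:6, 1000, TRUE)
  expect_equal(balanced_adjusted_rand_index(labels, clusters),
               adjusted_rand_index(labels, clusters), tolerance = 1e-12)
  expect_equal(balanced_adjusted_mutual_info(labels, clusters),
               adjusted_mutual_info(labels, clusters), tolerance = 1e-6)
})

test_that("balanced indices upweight errors in rare classes", {
  # splitting the dominant class hurts the plain index more than the
  # balanced one (the split class carries less mass after rebalancing) ...
  labels <- c(rep("common", 800), rep("rare", 200))
  split_common <- c(rep(1, 400), rep(2, 400), rep(3, 200))
  expect_gt(balanced_adjusted_rand_index(labels, split_common),
            adjusted_rand_index(labels, split_common))
  # ... while splitting the rare class hurts the balanced one more
  split_rare <- c(rep(1, 800), rep(2, 100), rep(3, 100))
  expect_lt(balanced_adjusted_rand_index(labels, split_rare),
            adjusted_rand_index(labels, split_rare))
})

test_that("silhouette and variance-ratio scores behave on reference geometries", {
  blobs <- make_blobs(n_per = 60, seed = 5)
  asw <- average_silhouette_width(blobs$labels, blobs$embedding)
  expect_gt(asw, 0.75) # tight, well-separated blobs

  mixed <- average_silhouette_width(sample(blobs$labels), blobs$embedding)
  expect_lt(mixed, asw)

  # embedding with intrinsic dimension <= 10 -> CVR = 1
  set.seed(6)
  low <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(rnorm(3 * 15), 3, 15)
  expect_equal(cumulative_variance_ratio(low), 1, tolerance = 1e-9)
  full <- matrix(rnorm(200 * 20), 200, 20)
  expect_lt(cumulative_variance_ratio(full), 1)
})

test_that("the resolution scan finds the label-matched clustering of 4 blobs", {
  blobs <- make_blobs(n_per = 100, seed = 7)
  scan <- optimal_resolution_scan(blobs$embedding, blobs$labels,
                                  resolution_grid = seq(0.02, 1, by = 0.02),
                                  seed = 8)
  expect_equal(scan$n_clusters, 4)
  expect_equal(min(scan$scan$diff), 0)
  scores <- partition_scores(scan$clusters, blobs$labels, blobs$embedding)
  expect_gt(scores[["ari"]], 0.95)
  expect_gt(scores[["asw"]], 0.75)

  # a one-point grid returns that resolution; ties resolve to the lowest
  single <- optimal_resolution_scan(blobs$embedding, blobs$labels,
                                    resolution_grid = 0.5, seed = 9)
  expect_equal(single$resolution, 0.5)
  first_best <- scan$scan$resolution[scan$scan$diff == min(scan$scan$diff)][1]
  expect_equal(scan$resolution, first_best)
})

test_that("one-vs-rest DE detects planted markers and respects its filters", {
  set.seed(10)
  nc <- 600
  labels <- rep(c("A", "B"), c(500, 100))
  m <- matrix(rpois(nc * 30, 5), nc, 30)
  m[labels == "A", 1] <- rpois(500, 40) # 8-fold marker for A
  colnames(m) <- c("marker", paste0("g", 2:30))
  ds <- kit_dataset(m, paste0("c", 1:nc),
                    data.frame(symbol = colnames(m), length_bp = 1,
                               gc_fraction = 0.5, is_mt = FALSE,
                               is_rp = FALSE), "k",
                    cell_labels = labels)
  hits <- vapply(1:10, function(s) {
    deg <- deg_one_vs_rest(ds, n_subsample = 400, seed = s)
    "marker" %in% deg$genes[["A"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # equal expression everywhere -> no DEGs at all
  flat <- kit_dataset(matrix(rpois(nc * 30, 5), nc, 30,
                             dimnames = list(NULL, paste0("g", 1:30))),
                      paste0("c", 1:nc),
                      data.frame(symbol = paste0("g", 1:30), length_bp = 1,
                                 gc_fraction = 0.5, is_mt = FALSE,
                                 is_rp = FALSE), "k", cell_labels = labels)
  deg0 <- deg_one_vs_rest(flat, n_subsample = NULL, seed = 1)
  expect_equal(sum(deg0$counts), 0)
})

test_that("cell types below 10 cells are excluded from DE testing", {
  labels <- rep(c("A", "B", "tiny"), c(200, 100, 9))
  n <- length(labels)
  m <- matrix(rpois(n * 10, 5), n, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  ds <- kit_dataset(m, paste0("c", 1:n),
                    data.frame(symbol = colnames(m), length_bp = 1,
                               gc_fraction = 0.5, is_mt = FALSE,
                               is_rp = FALSE), "k", cell_labels = labels)
  deg <- deg_one_vs_rest(ds, n_subsample = NULL, seed = 2)
  expect_false("tiny" %in% names(deg$counts))
  expect_setequal(names(deg$counts), c("A", "B"))
})

test_that("DE detection is monotone in the planted effect size", {
  set.seed(12)
  nc <- 300
  labels <- rep(c("A", "B"), each = nc / 2)
  count_degs <- function(fold) {
    m <- matrix(rpois(nc * 40, 4), nc, 40)
    m[labels == "A", 1:5] <- matrix(rpois(nc / 2 * 5, 4 * fold), nc / 2, 5)
    colnames(m) <- paste0("g", 1:40)
    ds <- kit_dataset(m, paste0("c", 1:nc),
                      data.frame(symbol = colnames(m), length_bp = 1,
                                 gc_fraction = 0.5, is_mt = FALSE,
                                 is_rp = FALSE), "k", cell_labels = labels)
    deg_one_vs_rest(ds, n_subsample = NULL, seed = 3)$counts[["A"]]
  }
  counts <- vapply(c(2, 8, 32), count_degs, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("the vectorized rank test agrees with wilcox.test on small data", {
  set.seed(13)
  nc <- 60
  labels <- rep(c("A", "B"), each = nc / 2)
  m <- matrix(rpois(nc * 5, 6), nc, 5, dimnames = list(NULL, paste0("g", 1:5)))
  m[labels == "A", 2] <- rpois(nc / 2, 20)
  ds <- kit_dataset(m, paste0("c", 1:nc),
                    data.frame(symbol = colnames(m), length_bp = 1,
                               gc_fraction = 0.5, is_mt = FALSE,
                               is_rp = FALSE), "k", cell_labels = labels)
  norm <- as.matrix(cpm_normalize(ds$counts))
  p_pkg <- sckit:::wilcox_vs_rest(norm, labels == "A")
  p_oracle <- vapply(1:5, function(j)
    wilcox.test(norm[labels == "A", j], norm[labels == "B", j],
                exact = FALSE, correct = FALSE)$p.value, numeric(1))
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
})

test_that("DEG z-scores standardize each cell type across kits", {
  counts <- matrix(c(10, 20, 30,
                     5, 5, 5,
                     0, 10, 50), nrow = 3, byrow = FALSE,
                   dimnames = list(paste0("kit", 1:3), c("T", "B", "NK")))
  z <- deg_zscores(counts)
  expect_equal(unname(z[, "B"]), c(0, 0, 0))
  for (ct in c("T", "NK")) {
    expect_equal(mean(z[, ct]), 0)
    expect_equal(sd(z[, ct]), 1)
  }
  # hand-computed column: (10,20,30) -> (-1, 0, 1)
  expect_equal(unname(z[, "T"]), c(-1, 0, 1))
})
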