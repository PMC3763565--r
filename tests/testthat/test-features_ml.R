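sd_list <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) {
    s <- spectral_density(mat[i, ])
    s$sample_id <- paste0("s", i)
    s
  })
}

test_that("identical samples collapse to one point with zero variance", {
  mat <- matrix(rep(rgamma(256, 2), 4), nrow = 4, byrow = TRUE)
  emb <- arpeggio_mds(sd_list(mat), k = 2)
  expect_equal(max(dist(emb$coordinates)), 0)
  expect_equal(emb$explained_variance_fraction, c(0, 0))
})

test_that("a rank-1 panel is captured entirely by the first component", {
  set.seed(4)
  base <- rgamma(256, 2)
  mat <- outer(c(1, 2, 5, 9), base)
  emb <- arpeggio_mds(sd_list(mat), k = 3)
  expect_equal(emb$explained_variance_fraction[1], 1, tolerance = 1e-9)
  expect_true(all(diff(emb$explained_variance_fraction) <= 1e-9))
})

test_that("k defaults to six and truncates with a warning", {
  set.seed(5)
  mat <- matrix(rgamma(10 * 128, 2), nrow = 10)
  emb <- arpeggio_mds(sd_list(mat))
  expect_identical(ncol(emb$coordinates), 6L)
  expect_lte(sum(emb$explained_variance_fraction), 1 + 1e-9)
  expect_warning(small <- arpeggio_mds(sd_list(mat[1:3, ]), k = 6),
                 "truncated")
  expect_identical(ncol(small$coordinates), 2L)
})

test_that("Davies-Bouldin matches the hand-computed worked example", {
  coords <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rep <- davies_bouldin(coords, c("A", "A", "B", "B"), n_boot = 0)
  expect_equal(rep$db_index, 0.1)
  expect_equal(unname(rep$dispersions), c(0.5, 0.5))
})

test_that("two singleton clusters give a zero index", {
  rep <- davies_bouldin(rbind(c(0, 0), c(3, 4)), c("A", "B"), n_boot = 0)
  expect_equal(rep$db_index, 0)
})

test_that("coincident centroids of spread clusters flag an infinite index", {
  coords <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  rep <- davies_bouldin(coords, c("A", "A", "B", "B"), n_boot = 0)
  expect_true(rep$infinite)
  expect_error(davies_bouldin(coords, rep("A", 4)), "2 clusters")
})

test_that("well-separated blobs get a tiny bootstrap p-value", {
  set.seed(12)
  coords <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
                  matrix(rnorm(100, 10, 0.1), ncol = 2))
  labels <- rep(c("A", "B"), each = 50)
  rep <- davies_bouldin(coords, labels, n_boot = 1000, seed = 3)
  expect_lte(rep$p_value, 0.001)
})

test_that("the index falls as centroids separate at fixed dispersion", {
  set.seed(13)
  cloud <- matrix(rnorm(60, 0, 0.5), ncol = 2)
  db_at <- function(gap)
    davies_bouldin(rbind(cloud, sweep(cloud, 2, c(gap, 0), `+`)),
                   rep(c("A", "B"), each = 30), n_boot = 0)$db_index
  vals <- vapply(c(2, 5, 10, 20), db_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("perfectly separated clouds classify with balanced accuracy 1", {
  set.seed(21)
  coords <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
                  matrix(rnorm(40, 8, 0.2), ncol = 2))
  labels <- rep(c("A", "B"), each = 20)
  rep <- knn_classify(coords, labels, n_boot = 20, seed = 2)
  expect_equal(rep$balanced_accuracy, 1)
  expect_lte(rep$p_value, 0.05)
})

test_that("random labels on one cloud give chance-level accuracy", {
  set.seed(22)
  coords <- matrix(rnorm(200), ncol = 2)
  accs <- vapply(1:20, function(i) {
    labels <- sample(rep(c("A", "B"), each = 50))
    knn_classify(coords, labels, n_boot = 0)$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("replicate groups are subsampled to one member", {
  set.seed(23)
  # replicate pairs are near-duplicates; leaking them makes LOO trivial
  base <- rbind(matrix(rnorm(20, 0, 1), ncol = 2),
                matrix(rnorm(20, 3, 1), ncol = 2))
  coords <- rbind(base, base + rnorm(40, 0, 0.01))
  labels <- rep(rep(c("A", "B"), each = 10), 2)
  groups <- rep(seq_len(20), 2)
  rep <- knn_classify(coords, labels, replicate_groups = groups,
                      n_rep = 5, n_boot = 0, seed = 4)
  # each retained set has one member per group: 20 predictions per rep
  expect_equal(sum(rep$confusion), 5 * 20)
})

test_that("single-sample labels are excluded with a warning", {
  coords <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  expect_warning(rep <- knn_classify(coords, c("A", "A", "B"), n_boot = 0),
                 "single sample")
  expect_equal(rep$balanced_accuracy, 1)  # only label A scored
})

test_that("AUC aggregation is 1 for perfect structure, 0.5 for noise", {
  block <- function(a, b) matrix(a, 10, 10) + diag(0, 10) * b
  D <- rbind(cbind(matrix(1, 10, 10), matrix(9, 10, 10)),
             cbind(matrix(9, 10, 10), matrix(1, 10, 10)))
  diag(D) <- 0
  labels <- rep(c("A", "B"), each = 10)
  res <- auc_aggregation(D, labels, n_rep = 5, seed = 1)
  expect_equal(res$median_auc, 1)

  set.seed(31)
  n <- 60
  R <- matrix(runif(n * n), n, n); R <- (R + t(R)) / 2; diag(R) <- 0
  res0 <- auc_aggregation(R, rep(c("A", "B"), each = 30), n_rep = 20,
                          seed = 2)
  expect_lt(abs(res0$median_auc - 0.5), 0.1)
})

test_that("tied distances earn midrank credit", {
  D <- matrix(1, 5, 5); diag(D) <- 0  # every distance identical
  res <- auc_aggregation(D, c("A", "A", "A", "B", "B"), n_rep = 2, seed = 1)
  expect_equal(res$per_sample$mean_auc[1], 0.5)
})

test_that("anchors exclude their own replicates from the ranking", {
  D <- matrix(5, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.01  # replicate pair artificially close
  labels <- c("A", "A", "A", "B")
  groups <- c("g1", "g1", "g2", "g3")
  expect_warning(res <- auc_aggregation(D, labels, replicate_groups = groups,
                                        n_rep = 4, seed = 3),
                 "excluded")
  # anchor 1 never sees its replicate 2: positives (sample 3) tie the
  # negative (sample 4) at distance 5 -> midrank AUC 0.5
  expect_equal(res$per_sample$mean_auc[1], 0.5)
})

test_that("Jaccard distance follows the printed overlap formula", {
  gr <- function(...) {
    iv <- list(...)
    GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = vapply(iv, `[`, numeric(1), 1) + 1,
                       end = vapply(iv, `[`, numeric(1), 2)))
  }
  a <- peak_set(gr(c(0, 100), c(200, 300)), "a")
  b <- peak_set(gr(c(50, 150), c(400, 500)), "b")
  expect_equal(jaccard_peak_distance(a, b), 2 / 3)
  expect_equal(jaccard_peak_distance(b, a), 2 / 3)

  expect_equal(jaccard_peak_distance(a, a), 0)
  disjoint <- peak_set(gr(c(1000, 1100)), "d")
  expect_equal(jaccard_peak_distance(a, disjoint), 1)
  empty <- peak_set(GenomicRanges::GRanges(), "e")
  expect_error(jaccard_peak_distance(empty, empty), "undefined")
  expect_gte(jaccard_peak_distance(a, b), 0)
  expect_lte(jaccard_peak_distance(a, b), 1)
})

test_that("spectral correlation distance is symmetric with zero diagonal", {
  set.seed(41)
  mat <- matrix(rgamma(5 * 128, 2), nrow = 5)
  D <- spectral_correlation_distance(sd_list(mat))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), numeric(5))
})
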