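test_that("mutual reachability matches hand evaluation on 1-D points", {
  X <- matrix(c(0, 0, 1, 0, 5, 0), 3, 2, byrow = TRUE)
  cfg <- clustering_config(min_cluster_size = 2, min_samples = 1)
  M <- mutual_reachability(X, cfg)
  expect_equal(unname(attr(M, "core_distances")), c(1, 1, 4))
  expect_equal(M[1, 2], 1)
  expect_equal(M[2, 3], 4)
  expect_equal(M[1, 3], 5)
  expect_equal(M, t(M))
})

test_that("coincident points have zero core distance at k = 1", {
  X <- matrix(0, 2, 2)
  M <- mutual_reachability(X, clustering_config(min_cluster_size = 2,
                                                min_samples = 1))
  expect_equal(unname(attr(M, "core_distances")), c(0, 0))
  expect_equal(M[1, 2], 0)
})

test_that("mutual reachability matches a brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 3), 10, 3)
    k <- 3
    M <- mutual_reachability(X, clustering_config(min_cluster_size = 2,
                                                  min_samples = k))
    ref <- oracle_mreach(X, k)
    expect_equal(unname(M[, ]), ref, tolerance = 1e-12)
    expect_true(all(M >= as.matrix(dist(X)) - 1e-12))
  }
  expect_error(mutual_reachability(matrix(rnorm(10), 5, 2),
    clustering_config(min_cluster_size = 2, min_samples = 5)), "below")
})

test_that("two dense blobs are recovered exactly with no noise", {
  g <- generate_embeddings(2, 300, 5, separation = 10, seed = 42)
  res <- fit_clusters(g$embedding, clustering_config(min_cluster_size = 100))
  expect_equal(sort(unique(res$labels)), c(0L, 1L))
  expect_equal(ari(res$labels, g$gold_labels), 1)
  expect_lte(sum(res$labels == -1), 3)
})

test_that("undersized inputs are labelled noise with a warning", {
  set.seed(1)
  X <- matrix(runif(100), 50, 2)
  expect_warning(res <- fit_clusters(X, clustering_config(100)), "noise")
  expect_true(all(res$labels == -1))
})

test_that("labels partition points into clusters plus noise", {
  g <- generate_embeddings(3, 240, 4, separation = 8,
                           outlier_fraction = 0.1, seed = 9)
  res <- fit_clusters(g$embedding, clustering_config(min_cluster_size = 50))
  labs <- res$labels
  m <- length(unique(labs[labs >= 0]))
  expect_true(all(labs %in% c(-1L, seq_len(m) - 1L)))
  for (cl in unique(labs[labs >= 0])) {
    expect_gte(sum(labs == cl), 50)
  }
})

test_that("raising min_cluster_size never increases the cluster count", {
  g <- generate_embeddings(4, 400, 4, separation = 8, seed = 12)
  counts <- sapply(c(30, 60, 110, 250), function(mcs) {
    res <- suppressWarnings(
      fit_clusters(g$embedding, clustering_config(min_cluster_size = mcs)))
    length(unique(res$labels[res$labels >= 0]))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("outlier scores are core distance over cluster mean", {
  res <- fake_cluster_result(c(0, 0, 0), core = c(1, 1, 2))
  expect_equal(unname(res$outlier_scores), c(0.75, 0.75, 1.5))
  # member at the cluster mean scores exactly 1
  res2 <- fake_cluster_result(c(0, 0, -1), core = c(2, 2, 9))
  expect_equal(unname(res2$outlier_scores), c(1, 1, NA))
})

test_that("outlier scores average to one within every fitted cluster", {
  g <- generate_embeddings(2, 260, 3, separation = 9, seed = 21)
  res <- fit_clusters(g$embedding, clustering_config(min_cluster_size = 80))
  for (cl in unique(res$labels[res$labels >= 0])) {
    expect_equal(mean(res$outlier_scores[res$labels == cl]), 1,
                 tolerance = 1e-12)
  }
  expect_true(all(is.na(res$outlier_scores[res$labels == -1])))
  expect_true(all(res$outlier_scores >= 0, na.rm = TRUE))
})

test_that("clustering is deterministic for a fixed input order", {
  g <- generate_embeddings(3, 200, 4, separation = 7, seed = 5)
  cfg <- clustering_config(min_cluster_size = 50)
  r1 <- fit_clusters(g$embedding, cfg)
  r2 <- fit_clusters(g$embedding, cfg)
  expect_identical(r1$labels, r2$labels)
})

test_that("per-cluster stabilities carry birth and death thresholds", {
  g <- generate_embeddings(2, 300, 5, separation = 10, seed = 42)
  res <- fit_clusters(g$embedding, clustering_config(min_cluster_size = 100))
  sel <- res$stabilities[res$stabilities$selected, ]
  expect_equal(nrow(sel), 2)
  expect_true(all(sel$stability > 0))
  expect_true(all(sel$lambda_birth > 0))
})
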