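test_that("topic distances behave at coincidence, orthogonality, singletons", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0.5, 0.5))
  rownames(X) <- paste0("p", 1:4)
  res <- fake_cluster_result(c(0L, 1L, 0L, -1L), ids = rownames(X))
  D <- topic_distances(embedding_matrix(rownames(X), X), res,
                       prm_config(distance = "cosine"))
  expect_equal(dim(D), c(4L, 2L))
  expect_equal(D[1, 1], 0, tolerance = 1e-12)       # equals its centroid
  expect_equal(D[2, 1], 1, tolerance = 1e-12)       # orthogonal unit vectors
  expect_equal(D[2, 2], 0, tolerance = 1e-12)       # singleton topic centroid
  expect_true(all(D >= 0))
})

test_that("euclidean distance option measures to the centroid", {
  X <- rbind(c(0, 0), c(2, 0), c(1, 5))
  rownames(X) <- paste0("p", 1:3)
  res <- fake_cluster_result(c(0L, 0L, -1L), ids = rownames(X))
  D <- topic_distances(embedding_matrix(rownames(X), X), res,
                       prm_config(distance = "euclidean"))
  expect_equal(unname(D[, 1]), c(1, 1, 5), tolerance = 1e-12)
})

test_that("soft assignment is a shift-invariant stable softmax", {
  # equal distances -> uniform row
  P <- soft_assign(matrix(2, 1, 4))
  expect_equal(unname(P$P[1, ]), rep(0.25, 4))
  # closed form: distances (0, ln 3) -> (0.75, 0.25)
  P2 <- soft_assign(matrix(c(0, log(3)), 1, 2))
  expect_equal(unname(P2$P[1, ]), c(0.75, 0.25), tolerance = 1e-12)
  # shifting a row by a constant changes nothing
  D <- matrix(runif(12), 3, 4)
  expect_equal(soft_assign(D + 7)$P, soft_assign(D)$P, tolerance = 1e-12)
  # rows sum to one even for extreme magnitudes
  P3 <- soft_assign(matrix(c(0, 800, 1600), 1, 3))
  expect_equal(sum(P3$P), 1, tolerance = 1e-9)
  expect_error(soft_assign(matrix(numeric(0), 1, 0)), "no topics")
})

test_that("reassignment touches only outliers above the strict threshold", {
  labels <- c(0L, 1L, -1L, -1L)
  res <- fake_cluster_result(labels)
  P <- structure(list(ids = paste0("p", 1:4), topics = c("0", "1"),
                      P = rbind(c(0.9, 0.1), c(0.2, 0.8),
                                c(0.14, 0.86), c(0.86, 0.14))),
                 class = "doc_topic_matrix")
  rownames(P$P) <- P$ids
  out <- reassign_outliers(res, P, prm_config(threshold = 0.86))
  # 0.86 is not > 0.86: both outliers stay noise under a strict threshold
  expect_equal(unname(out$labels), labels)
  out2 <- reassign_outliers(res, P, prm_config(threshold = 0.15))
  expect_equal(unname(out2$labels), c(0L, 1L, 1L, 0L))
  # non-outlier labels never change; outlier count never increases
  expect_equal(unname(out2$labels[1:2]), c(0L, 1L))
  expect_lte(sum(out2$labels == -1), sum(labels == -1))
})

test_that("a winning probability exactly at 0.14 stays noise at 0.15", {
  res <- fake_cluster_result(c(0L, rep(-1L, 1)))
  P <- structure(list(ids = c("p1", "p2"), topics = as.character(0:7),
                      P = rbind(c(0.3, rep(0.1, 7)),
                                c(0.14, 0.14, 0.14, 0.14, 0.14, 0.14,
                                  0.14, 0.02))),
                 class = "doc_topic_matrix")
  out <- reassign_outliers(res, P, prm_config(threshold = 0.15))
  expect_equal(unname(out$labels[2]), -1L)
})

test_that("reassignment with no outliers is a no-op", {
  res <- fake_cluster_result(c(0L, 1L, 0L))
  P <- soft_assign(matrix(runif(6), 3, 2, dimnames = list(NULL, c("0", "1"))))
  out <- reassign_outliers(res, P, prm_config())
  expect_identical(out$labels, res$labels)
})

test_that("argmax ties go to the lowest topic index", {
  res <- fake_cluster_result(c(0L, 1L, -1L))
  P <- structure(list(ids = paste0("p", 1:3), topics = c("0", "1"),
                      P = rbind(c(1, 0), c(0, 1), c(0.5, 0.5))),
                 class = "doc_topic_matrix")
  out <- reassign_outliers(res, P, prm_config(threshold = 0.15))
  expect_equal(unname(out$labels[3]), 0L)
})

test_that("planted outliers near a centroid are pulled back to it", {
  g <- generate_embeddings(3, 300, 4, separation = 9, seed = 31)
  res <- fit_clusters(g$embedding, clustering_config(min_cluster_size = 80))
  expect_gt(min(table(res$labels[res$labels >= 0])), 0)
  X <- g$embedding$vectors
  cents <- t(sapply(sort(unique(res$labels[res$labels >= 0])), function(t) {
    colMeans(X[res$labels == t, , drop = FALSE])
  }))
  set.seed(31)
  gen <- rep(0:2, each = 20)
  O <- cents[gen + 1, ] + matrix(rnorm(60 * 4, sd = 0.3), 60, 4)
  Xa <- rbind(X, O)
  rownames(Xa) <- c(rownames(X), paste0("o", 1:60))
  labs <- c(res$labels, rep(-1L, 60))
  resa <- fake_cluster_result(labs, ids = rownames(Xa))
  D <- topic_distances(embedding_matrix(rownames(Xa), Xa), resa, prm_config())
  out <- reassign_outliers(resa, soft_assign(D), prm_config())
  planted <- out$labels[301:360]
  expect_gte(mean(planted == gen), 0.9)
  expect_lt(sum(out$labels == -1), sum(labs == -1))
})

test_that("reassignment never increases the outlier rate", {
  for (seed in c(2, 13)) {
    g <- generate_embeddings(3, 240, 4, separation = 8,
                             outlier_fraction = 0.1, seed = seed)
    res <- suppressWarnings(
      fit_clusters(g$embedding, clustering_config(min_cluster_size = 40)))
    expect_true(any(res$labels >= 0))
    D <- topic_distances(g$embedding, res, prm_config())
    out <- reassign_outliers(res, soft_assign(D), prm_config())
    expect_lte(outlier_rate(out$labels)$rate,
               outlier_rate(res$labels)$rate)
  }
})
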