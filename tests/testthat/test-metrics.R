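test_that("silhouette matches hand evaluation on two tight pairs", {
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labs <- c(0L, 0L, 1L, 1L)
  s0 <- (10.05 - 0.1) / 10.05
  expect_equal(s0, 0.99005, tolerance = 1e-5)
  ref <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(silhouette_score(X, labs), ref, tolerance = 1e-12)
})

test_that("coincident clusters score at or below zero, noise excluded", {
  X <- matrix(rep(c(0, 0.01), each = 4), 8, 1)
  labs <- rep(c(0L, 1L), 4)
  expect_lte(silhouette_score(X, labs), 0)
  s <- silhouette_score(matrix(1:4, 4, 1), c(0L, 0L, -1L, -1L))
  expect_true(is.na(s))
  expect_match(attr(s, "reason"), "fewer than two")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(40), 20, 2)
    labs <- sample(0:2, 20, replace = TRUE)
    ref <- mean(cluster::silhouette(labs, stats::dist(X))[, "sil_width"])
    expect_equal(silhouette_score(X, labs), ref, tolerance = 1e-9)
  }
})

test_that("outlier rate reproduces the printed corpus-scale percentages", {
  labs <- c(rep(-1L, 17670), rep(0L, 64407 - 17670))
  r <- outlier_rate(labs)
  expect_equal(round(100 * r$rate, 2), 27.43)
  expect_equal(r$n_outliers, 17670)
  labs2 <- c(rep(-1L, 3368), rep(0L, 64407 - 3368))
  expect_equal(round(100 * outlier_rate(labs2)$rate, 2), 5.23)
  expect_equal(outlier_rate(c(0L, 1L))$rate, 0)
})

test_that("NPMI hits its closed-form anchor points", {
  # perfect co-occurrence
  docs <- toy_docs(list(c("a", "b"), c("a", "b"), c("z", "q")))
  expect_equal(as.numeric(npmi(list(c("a", "b")), docs)), 1)
  # independence: p1 = p2 = 1/2, joint 1/4 over 4 docs
  docs2 <- toy_docs(list(c("w1", "w2"), c("w1", "x"), c("w2", "y"),
                         c("z", "q")))
  expect_equal(as.numeric(npmi(list(c("w1", "w2")), docs2)), 0,
               tolerance = 1e-12)
  # never co-occurring
  docs3 <- toy_docs(list(c("a", "x"), c("b", "y"), c("a", "z")))
  expect_equal(as.numeric(npmi(list(c("a", "b")), docs3)), -1)
})

test_that("NPMI is symmetric and invariant to corpus duplication", {
  set.seed(4)
  docs <- toy_docs(lapply(1:12, function(i) sample(letters[1:6], 3)))
  t1 <- npmi(list(c("a", "b", "c")), docs)
  t2 <- npmi(list(c("c", "b", "a")), docs)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-12)
  docs2 <- toy_docs(c(docs$tokens, docs$tokens),
                    ids = paste0("d", 1:24))
  expect_equal(as.numeric(npmi(list(c("a", "b", "c")), docs2)),
               as.numeric(t1), tolerance = 1e-12)
})

test_that("absent words are skipped and counted in coverage", {
  docs <- toy_docs(list(c("a", "b"), c("a", "b")))
  r <- npmi(list(c("a", "b", "ghost")), docs)
  expect_equal(as.numeric(r), 1)
  expect_equal(attr(r, "coverage"), 1 / 3)
})

test_that("topic diversity counts distinct keyword slots", {
  expect_equal(topic_diversity(list(c("a", "b"), c("c", "d"))), 1)
  k10 <- paste0("w", 1:10)
  expect_equal(topic_diversity(rep(list(k10), 4)), 0.25)
  t1 <- paste0("a", 1:10); t2 <- c(paste0("a", 1:5), paste0("b", 1:5))
  expect_equal(topic_diversity(list(t1, t2)), 0.75)
})

test_that("perplexity anchors: one-hot, uniform, closed form", {
  mk <- function(M, n, p) structure(list(
    ids = paste0("d", 1:n), topics = as.character(seq_len(M) - 1),
    P = matrix(p, n, M, byrow = TRUE)), class = "doc_topic_matrix")
  expect_equal(perplexity_score(mk(3, 4, c(1, 0, 0)), rep(0L, 4)), 1)
  expect_equal(perplexity_score(mk(5, 6, rep(0.2, 5)), rep(2L, 6)), 5,
               tolerance = 1e-12)
  expect_equal(perplexity_score(mk(2, 3, c(0.75, 0.25)), rep(0L, 3)),
               4 / 3, tolerance = 1e-12)
})

test_that("lexical diversity counts distinct per-document top terms", {
  docs <- toy_docs(list(c("a", "b"), c("c", "d"), c("a", "b")))
  # 6 slots, 4 distinct at m = 2
  expect_equal(lexical_diversity(docs, c(0L, 0L, 0L), per_doc_top_m = 2),
               4 / 6, tolerance = 1e-12)
  # all slots distinct
  docs2 <- toy_docs(list(c("a", "b"), c("c", "d")))
  expect_equal(lexical_diversity(docs2, c(0L, 0L), per_doc_top_m = 2), 1)
  # single-document topic is unique by construction
  expect_equal(lexical_diversity(toy_docs(list(c("x", "y", "z"))), 0L,
                                 per_doc_top_m = 3), 1)
})

test_that("centroid cosine matches the right-angle geometry example", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(centroid_cosine(X, c(0L, 0L)), cos(pi / 4),
               tolerance = 1e-12)
  expect_equal(cos(pi / 4), 0.70711, tolerance = 1e-5)
  # identical documents coincide with their centroid
  expect_equal(centroid_cosine(rbind(c(1, 2), c(1, 2)), c(0L, 0L)), 1,
               tolerance = 1e-12)
  set.seed(2)
  X2 <- matrix(rnorm(30), 15, 2)
  v <- centroid_cosine(X2, sample(0:1, 15, TRUE))
  expect_true(v >= -1 && v <= 1)
})

test_that("the full report assembles finite values on a real fixture", {
  sc <- generate_corpus(small_spec(seed = 2))
  cl <- clean_corpus(sc$docs)
  gold <- sc$gold_labels[cl$id]
  emb <- embed_documents(cl, embedder_spec(dim = 32, seed = 2))
  tw <- ctfidf(cl, gold)
  kw <- topic_keywords(tw, top_k = 10)
  D <- topic_distances(emb, fake_cluster_result(gold, ids = cl$id),
                       prm_config())
  rep <- evaluate_metrics(cl, gold, emb, emb, kw, P = soft_assign(D),
                          tw = tw)
  expect_true(is.finite(rep$npmi))
  expect_true(rep$td > 0 && rep$td <= 1)
  expect_gte(rep$perplexity, 1)
  expect_true(rep$outlier_rate >= 0 && rep$outlier_rate <= 1)
  expect_equal(rep$n_topics, 3)
})
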