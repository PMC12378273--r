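test_that("class-based TF-IDF matches hand evaluation", {
  # N = 4 docs; term w appears twice in topic 0 whose token total is 10
  docs <- toy_docs(list(
    c("w", "w", "a", "b", "c", "d", "e", "f", "g", "h"),
    c("x", "y"), c("x", "z"), c("y", "z")))
  labels <- c(0L, 1L, 1L, 1L)
  tw <- ctfidf(docs, labels)
  expect_equal(tw$weights["0", "w"], 0.2 * log(4), tolerance = 1e-12)
  expect_equal(0.2 * log(4), 0.27726, tolerance = 1e-4)
  # term absent from a topic scores zero there
  expect_equal(tw$weights["1", "w"], 0)
})

test_that("a term in every document has zero weight everywhere", {
  docs <- toy_docs(list(c("common", "a"), c("common", "b"),
                        c("common", "c")))
  tw <- ctfidf(docs, c(0L, 0L, 1L))
  expect_equal(unname(tw$weights[, "common"]), c(0, 0))
})

test_that("noise documents count toward N and df but not topic TF", {
  docs <- toy_docs(list(c("w", "a"), c("w", "b"), c("q", "b")))
  tw <- ctfidf(docs, c(0L, -1L, 0L))
  expect_equal(tw$n_docs, 3)
  expect_equal(unname(tw$doc_freq["w"]), 2L)       # noise doc still counted
  expect_equal(unname(tw$tf["0", "w"]), 1)         # not its occurrences
  expect_equal(tw$weights["0", "w"], 1 / 4 * log(3 / 2), tolerance = 1e-12)
})

test_that("the weight matrix matches a literal two-loop reference", {
  set.seed(11)
  vocab <- c(paste0("t", 1:12), "sleep", "stress")
  docs <- toy_docs(lapply(1:30, function(i) {
    sample(vocab, sample(3:8, 1), replace = TRUE)
  }))
  labels <- sample(c(-1L, 0L, 1L, 2L), 30, replace = TRUE)
  tw <- ctfidf(docs, labels)
  ref <- oracle_ctfidf(docs, labels)
  expect_equal(unname(tw$weights), unname(ref), tolerance = 1e-9)
})

test_that("rank decay follows the printed closed form", {
  # rank-1 term, alpha 0.05: multiplier e^-0.05
  docs <- toy_docs(list(rep("top", 5), c("top", "mid"), c("rare", "mid")))
  tw <- ctfidf(docs, c(0L, 0L, 1L))
  cfg <- pdr_config(alpha = 0.05, decile = 0.25, boost = 1.5,
                    dictionary = character(0))
  out <- pdr_weights(tw, cfg)
  expect_equal(unname(out$multipliers["top"]), exp(-0.05), tolerance = 1e-12)
  expect_equal(exp(-0.05), 0.951229, tolerance = 1e-6)
  # alpha = 0 leaves decile weights unchanged
  out0 <- pdr_weights(tw, pdr_config(alpha = 0, decile = 0.25,
                                     dictionary = character(0)))
  expect_equal(out0$weights, tw$weights)
})

test_that("dictionary terms outside the decile are boosted by 1.5", {
  docs <- toy_docs(list(c(rep("filler", 9), "bullying"),
                        c("filler", "other")))
  tw <- ctfidf(docs, c(0L, 1L))
  tw$weights["0", "bullying"] <- 0.4   # probe value
  out <- pdr_weights(tw, pdr_config(decile = 0.3))  # decile = {filler}
  expect_true("bullying" %in% out$dictionary_terms)
  expect_false("bullying" %in% out$decile_terms)
  expect_equal(out$weights["0", "bullying"], 0.6, tolerance = 1e-12)
})

test_that("regularization is the identity off the decile and dictionary", {
  set.seed(5)
  docs <- toy_docs(lapply(1:20, function(i) {
    sample(paste0("v", 1:40), 8, replace = TRUE)
  }))
  tw <- ctfidf(docs, rep(c(0L, 1L), 10))
  cfg <- pdr_config(dictionary = character(0))
  out <- pdr_weights(tw, cfg)
  untouched <- setdiff(tw$vocabulary, out$decile_terms)
  expect_equal(out$weights[, untouched], tw$weights[, untouched])
  # monotone decay within the decile under the printed direction
  ranks <- match(out$decile_terms,
                 tw$vocabulary[order(-tw$corpus_tf, tw$vocabulary)])
  mults <- out$multipliers[out$decile_terms]
  expect_true(all(diff(mults[order(ranks)]) < 0))
})

test_that("decay and boost compose for terms that are both", {
  docs <- toy_docs(list(c(rep("sleep", 6), "a"), c("b", "c")))
  tw <- ctfidf(docs, c(0L, 1L))
  out <- pdr_weights(tw, pdr_config(alpha = 0.1, decile = 0.25))
  expect_equal(unname(out$multipliers["sleep"]), exp(-0.1) * 1.5,
               tolerance = 1e-12)
  expect_true(all(out$weights >= 0))
})

test_that("reduction-ratio and boost-rate diagnostics are reproducible", {
  set.seed(6)
  docs <- toy_docs(lapply(1:25, function(i) {
    c(sample(paste0("f", 1:10), 4, TRUE), sample(c("sleep", "stress",
                                                   paste0("r", 1:30)), 4))
  }))
  tw <- ctfidf(docs, rep(c(0L, 1L), length.out = 25))
  cfg <- pdr_config()
  out <- pdr_weights(tw, cfg)
  V <- length(tw$vocabulary)
  ord <- order(-tw$corpus_tf, tw$vocabulary)
  n_dec <- ceiling(0.1 * V)
  ref_red <- mean(exp(-0.05 * seq_len(n_dec)))
  expect_equal(out$diagnostics$reduction_ratio, ref_red, tolerance = 1e-12)
  expect_gte(out$diagnostics$boosting_rate, 1)
})

test_that("MMR reduces to relevance ranking at lambda = 1", {
  cand <- data.frame(term = c("a", "b", "c"), relevance = c(0.2, 0.9, 0.5))
  sim <- matrix(0.5, 3, 3, dimnames = list(cand$term, cand$term))
  expect_equal(mmr_select(cand, sim, lambda = 1, k = 2), c("b", "c"))
})

test_that("MMR trades redundancy for diversity as documented", {
  cand <- data.frame(term = c("t1", "t2", "t3"),
                     relevance = c(0.9, 0.8, 0.5))
  sim <- diag(3)
  dimnames(sim) <- list(cand$term, cand$term)
  sim["t1", "t2"] <- sim["t2", "t1"] <- 0.9
  expect_equal(mmr_select(cand, sim, lambda = 0.5, k = 3),
               c("t1", "t3", "t2"))
  # exhaustion: k = |candidates| selects everything exactly once
  sel <- mmr_select(cand, sim, lambda = 0.3, k = 3)
  expect_setequal(sel, cand$term)
  expect_equal(anyDuplicated(sel), 0)
  expect_warning(mmr_select(cand, sim, k = 5), "all")
})

test_that("topic keyword lists are unique, ranked and sized to top_k", {
  sc <- generate_corpus(small_spec(seed = 3))
  cl <- clean_corpus(sc$docs)
  gold <- sc$gold_labels[cl$id]
  tw <- pdr_weights(ctfidf(cl, gold))
  vocab <- unique(unlist(cl$tokens))
  tv <- shorttopics:::token_vectors(vocab, 32, 3)
  kw <- topic_keywords(tw, tv, top_k = 10)
  expect_equal(length(kw), 3)
  for (df in kw) {
    expect_equal(nrow(df), 10)
    expect_equal(anyDuplicated(df$term), 0)
  }
})
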