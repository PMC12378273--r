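# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# A small planted-topic corpus that keeps pipeline-level tests fast.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_topics = 3, docs_per_topic = 100, vocab_generic = 80,
                 vocab_per_topic = 25, seed = seed, ...)
}

small_run_config <- function(seed = 1, ...) {
  run_config(seed = seed,
             reduction = reduction_config(n_neighbors = 15, seed = seed,
                                          candidate_dims = 2:8),
             clustering = clustering_config(min_cluster_size = 60),
             ...)
}

# Tiny clean corpus from explicit token lists.
toy_docs <- function(token_lists, ids = NULL) {
  ids <- ids %||% paste0("d", seq_along(token_lists))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$tokens <- token_lists
  out$text_norm <- vapply(token_lists, paste, "", collapse = " ")
  class(out) <- c("clean_corpus", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Minimal cluster_result for stages downstream of clustering.
fake_cluster_result <- function(labels, core = NULL, ids = NULL) {
  ids <- ids %||% paste0("p", seq_along(labels))
  core <- core %||% rep(1, length(labels))
  shorttopics:::new_cluster_result(
    ids, as.integer(labels), core,
    data.frame(cluster = integer(0), stability = numeric(0),
               lambda_birth = numeric(0), lambda_death = numeric(0),
               size = integer(0)))
}
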