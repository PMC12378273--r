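## End-to-end orchestration: preprocessing, embedding, deduplication,
## reduction (with optional silhouette-driven dimension selection),
## density clustering, keyword extraction (with optional popularity
## regularization), probabilistic outlier reassignment, metrics, and
## artifact writing. The three optimization stages are independent
## toggles, supporting the 2^3 ablation grid.

#' Configuration of a full pipeline run
#'
#' @param pdr Enable the popularity-deviation regularizer? Default `TRUE`.
#' @param ddeo Enable silhouette-driven dimension selection? Default
#'   `TRUE`; when disabled, the reduction uses the fixed baseline
#'   dimensionality 5.
#' @param prm Enable probabilistic outlier reassignment? Default `TRUE`;
#'   when disabled the document-topic probability matrix is still emitted.
#' @param embedder An [embedder_spec()].
#' @param reduction A [reduction_config()].
#' @param clustering A [clustering_config()].
#' @param pdr_cfg A [pdr_config()].
#' @param prm_cfg A [prm_config()].
#' @param dedup_epsilon Cosine threshold for near-duplicate removal
#'   (default 0.95); `NA` disables embedding dedup.
#' @param top_k Keywords per topic (default 10).
#' @param mmr_lambda MMR trade-off (default 0.5).
#' @param per_doc_top_m Per-document terms for lexical diversity
#'   (default 3).
#' @param recompute_keywords Recompute keywords after reassignment?
#'   Default `FALSE` (keywords reflect the hard clustering).
#' @param seed Master seed for every stochastic component.
#' @return Object of class `run_config`.
#' @export
run_config <- function(pdr = TRUE, ddeo = TRUE, prm = TRUE,
                       embedder = NULL, reduction = NULL, clustering = NULL,
                       pdr_cfg = NULL, prm_cfg = NULL,
                       dedup_epsilon = 0.95, top_k = 10, mmr_lambda = 0.5,
                       per_doc_top_m = 3, recompute_keywords = FALSE,
                       seed = 1) {
  seed <- as.integer(seed)
  structure(list(
    pdr = isTRUE(pdr), ddeo = isTRUE(ddeo), prm = isTRUE(prm),
    embedder = embedder %||% embedder_spec(seed = seed),
    reduction = reduction %||% reduction_config(seed = seed),
    clustering = clustering %||% clustering_config(),
    pdr_cfg = pdr_cfg %||% pdr_config(),
    prm_cfg = prm_cfg %||% prm_config(),
    dedup_epsilon = dedup_epsilon, top_k = top_k,
    mmr_lambda = mmr_lambda, per_doc_top_m = per_doc_top_m,
    recompute_keywords = isTRUE(recompute_keywords), seed = seed),
    class = "run_config")
}

#' Run the full topic-modeling pipeline
#'
#' @param corpus A corpus file path (CSV/JSONL), a data frame with columns
#'   `id`, `text`, or a `synthetic_corpus`.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all artifacts (labels,
#'   keywords, probabilities, metrics, manifest) are written there.
#' @return Object of class `pipeline_run`: list with `clean`, `embedding`,
#'   `reduced`, `ddeo`, `clusters` (pre-reassignment), `final_labels`,
#'   `term_weights`, `keywords`, `doc_topic`, `metrics`,
#'   `outlier_rate_before`, `outlier_rate_after`, and `config`.
#' @export
run_pipeline <- function(corpus, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  raw <- resolve_corpus(corpus)

  clean <- clean_corpus(raw)
  if (nrow(clean) == 0) stop("no documents after preprocessing")
  emb <- embed_documents(clean, config$embedder)
  clean <- clean[clean$id %in% emb$ids, , drop = FALSE]

  use_emb_dedup <- !is.na(config$dedup_epsilon)
  clean <- deduplicate(clean, vectors = emb,
                       epsilon = if (use_emb_dedup) config$dedup_epsilon else 1,
                       use_hash = TRUE, use_embedding = use_emb_dedup)
  dedup_report <- attr(clean, "dedup_report")
  emb <- embedding_matrix(clean$id,
                          emb$vectors[match(clean$id, emb$ids), ,
                                      drop = FALSE])
  if (nrow(clean) == 0) stop("no documents after preprocessing")

  ddeo_res <- NULL
  if (config$ddeo) {
    ddeo_res <- select_dimension(emb, config$reduction, config$clustering)
    reduced <- ddeo_res$reduced
  } else {
    reduced <- reduce_embeddings(emb, 5L, config$reduction)
  }

  clusters <- fit_clusters(reduced, config$clustering)
  labels0 <- clusters$labels
  or_before <- outlier_rate(labels0)

  token_vecs <- NULL
  if (config$embedder$backend == "hash") {
    vocab <- unique(unlist(clean$tokens, use.names = FALSE))
    token_vecs <- token_vectors(vocab, config$embedder$dim,
                                config$embedder$seed)
  }

  has_topics <- any(labels0 >= 0)
  tw <- NULL; kw <- list(); P <- NULL
  final <- clusters
  if (has_topics) {
    tw <- ctfidf(clean, labels0)
    if (config$pdr) tw <- pdr_weights(tw, config$pdr_cfg)
    kw <- topic_keywords(tw, token_vecs, top_k = config$top_k,
                         mmr_lambda = config$mmr_lambda)
    dist_pts <- if (config$prm_cfg$space == "reduced") reduced else emb
    D <- topic_distances(dist_pts, clusters, config$prm_cfg)
    P <- soft_assign(D)
    if (config$prm) {
      final <- reassign_outliers(clusters, P, config$prm_cfg)
      if (config$recompute_keywords) {
        tw <- ctfidf(clean, final$labels)
        if (config$pdr) tw <- pdr_weights(tw, config$pdr_cfg)
        kw <- topic_keywords(tw, token_vecs, top_k = config$top_k,
                             mmr_lambda = config$mmr_lambda)
      }
    }
  } else {
    warning("no clusters found; all documents are noise")
  }
  or_after <- outlier_rate(final$labels)

  metrics <- NULL
  if (has_topics) {
    cs_vectors <- emb
    if (config$pdr && !is.null(token_vecs)) {
      cs_vectors <- repool_vectors(clean, final$labels, tw, token_vecs, emb)
    }
    metrics <- evaluate_metrics(clean, final$labels, reduced, cs_vectors,
                                kw, P = P, tw = tw, top_k = config$top_k,
                                per_doc_top_m = config$per_doc_top_m)
  }

  run <- structure(list(
    clean = clean, embedding = emb, reduced = reduced, ddeo = ddeo_res,
    clusters = clusters, final_labels = final$labels,
    term_weights = tw, keywords = kw, doc_topic = P, metrics = metrics,
    outlier_rate_before = or_before, outlier_rate_after = or_after,
    dedup_report = dedup_report,
    reassignment_report = attr(final, "reassignment_report"),
    config = config), class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", nrow(x$clean), " documents, ",
      length(unique(x$final_labels[x$final_labels >= 0])), " topics, OR ",
      sprintf("%.2f%%", 100 * x$outlier_rate_before$rate), " -> ",
      sprintf("%.2f%%", 100 * x$outlier_rate_after$rate), "\n", sep = "")
  invisible(x)
}

resolve_corpus <- function(corpus) {
  if (inherits(corpus, "synthetic_corpus")) return(corpus$docs)
  if (is.character(corpus) && length(corpus) == 1) {
    return(read_corpus(corpus))
  }
  if (is.data.frame(corpus)) return(corpus)
  stop("corpus must be a path, a data frame, or a synthetic_corpus")
}

## Document vectors re-pooled as weight-weighted token means, so the
## centroid-cosine metric can feel the keyword regularization. Weights are
## the document's topic row of the (regularized) term-weight matrix;
## documents without positive weight mass keep their plain mean vector.
repool_vectors <- function(docs, labels, tw, token_vecs, fallback) {
  V <- fallback$vectors
  for (i in seq_len(nrow(docs))) {
    lab <- labels[i]
    if (lab < 0 || !as.character(lab) %in% rownames(tw$weights)) next
    tk <- docs$tokens[[i]]
    tk <- tk[tk %in% rownames(token_vecs)]
    if (length(tk) == 0) next
    w <- tw$weights[as.character(lab), tk]
    if (sum(w) <= 0) next
    V[i, ] <- colSums(token_vecs[tk, , drop = FALSE] * w) / sum(w)
  }
  embedding_matrix(fallback$ids, V)
}

#' Write run artifacts to a directory
#'
#' Writes `labels.tsv`, `keywords.tsv`, `doc_topic.tsv`, `metrics.json`,
#' `ddeo_scores.tsv`, `dedup_report.tsv`, `reassignment.tsv` and
#' `manifest.json`.
#'
#' @param run A `pipeline_run`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labs <- data.frame(id = names(run$final_labels),
                     label = unname(run$final_labels),
                     outlier_score = unname(run$clusters$outlier_scores))
  write_tsv(labs, file.path(out_dir, "labels.tsv"))
  kt <- keywords_table(run$keywords)
  if (!is.null(kt)) write_tsv(kt, file.path(out_dir, "keywords.tsv"))
  if (!is.null(run$doc_topic)) {
    dt <- data.frame(id = run$doc_topic$ids, run$doc_topic$P,
                     check.names = FALSE)
    write_tsv(dt, file.path(out_dir, "doc_topic.tsv"))
  }
  if (!is.null(run$metrics)) {
    jsonlite::write_json(unclass(run$metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(run$ddeo)) {
    write_tsv(run$ddeo$table, file.path(out_dir, "ddeo_scores.tsv"))
  }
  if (!is.null(run$dedup_report) && nrow(run$dedup_report)) {
    write_tsv(run$dedup_report, file.path(out_dir, "dedup_report.tsv"))
  }
  if (!is.null(run$reassignment_report) &&
      nrow(run$reassignment_report)) {
    write_tsv(run$reassignment_report,
              file.path(out_dir, "reassignment.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("shorttopics")),
    r_version = R.version.string,
    seed = run$config$seed,
    toggles = list(pdr = run$config$pdr, ddeo = run$config$ddeo,
                   prm = run$config$prm),
    config_hash = string_hash(paste(deparse(run$config), collapse = "")),
    n_documents = nrow(run$clean),
    n_topics = length(unique(run$final_labels[run$final_labels >= 0])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Parameter sweep over pipeline settings
#'
#' Runs the pipeline once per grid point (the Cartesian product of the
#' supplied value vectors) and tabulates topic count, outlier rate and all
#' metrics. Supported keys: `min_cluster_size`, `alpha`, `threshold`,
#'   `candidate_dims` (a list of integer vectors).
#'
#' @param corpus As in [run_pipeline()].
#' @param config Base [run_config()].
#' @param grid Named list mapping parameter names to value vectors.
#' @return Data frame with one row per grid point: the varied parameters
#'   plus `n_topics`, `outlier_rate`, `npmi`, `td`, `perplexity`,
#'   `silhouette`, `lexical_diversity`, `centroid_cosine`, `chosen_dim`.
#' @export
run_sweep <- function(corpus, config = run_config(), grid) {
  supported <- c("min_cluster_size", "alpha", "threshold", "candidate_dims")
  if (!length(grid) || is.null(names(grid)) ||
      !all(names(grid) %in% supported)) {
    stop("grid keys must be among: ", paste(supported, collapse = ", "))
  }
  combos <- expand.grid(lapply(grid, seq_along))
  rows <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    cfg <- config
    vals <- list()
    for (key in names(grid)) {
      v <- grid[[key]][[combos[r, key]]]
      vals[[key]] <- if (key == "candidate_dims") {
        paste(range(v), collapse = "-")
      } else v
      cfg <- switch(key,
        min_cluster_size = {
          cfg$clustering <- clustering_config(
            min_cluster_size = v,
            metric = cfg$clustering$metric); cfg
        },
        alpha = {
          cfg$pdr_cfg$alpha <- v; cfg
        },
        threshold = {
          cfg$prm_cfg$threshold <- v; cfg
        },
        candidate_dims = {
          cfg$reduction$candidate_dims <- sort(unique(as.integer(v))); cfg
        })
    }
    run <- suppressWarnings(run_pipeline(corpus, cfg))
    m <- run$metrics
    rows[[r]] <- data.frame(
      vals,
      n_topics = length(unique(run$final_labels[run$final_labels >= 0])),
      outlier_rate = run$outlier_rate_after$rate,
      outlier_rate_raw = run$outlier_rate_before$rate,
      npmi = if (is.null(m)) NA_real_ else m$npmi,
      td = if (is.null(m)) NA_real_ else m$td,
      perplexity = if (is.null(m)) NA_real_ else m$perplexity,
      silhouette = if (is.null(m)) NA_real_ else m$silhouette,
      lexical_diversity = if (is.null(m)) NA_real_ else m$lexical_diversity,
      centroid_cosine = if (is.null(m)) NA_real_ else m$centroid_cosine,
      chosen_dim = if (is.null(run$ddeo)) 5L else run$ddeo$chosen_dim)
  }
  do.call(rbind, rows)
}
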